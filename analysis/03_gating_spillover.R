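#!/usr/bin/env Rscript
# How segmentation spillover corrupts hierarchical gating: sweep the
# spillover fraction and measure how often truth-endothelial cells are
# gated as epithelium, versus the robustness of full-marker clustering.

suppressPackageStartupMessages(library(codexbench))

lams <- c(0, 0.2, 0.4, 0.6, 0.8)
rows <- list()
for (lam in lams) {
  ds <- build_default_scenario(3000, seed = 7,
                               noise = noise_model(spillover_lambda = lam))
  tr <- truth_annotation(ds)
  rate <- spillover_misassignment_rate(ds)
  fg <- f_scores(tr, apply_gating_tree(ds$cell_table, default_gating_tree()),
                 1, ds$hierarchy)
  z <- apply_treatment(intensity_matrix(ds$cell_table), "z")
  ann <- annotate_by_profile(cluster_leiden(z, seed = 77), z,
                             expected_profiles())
  fc <- f_scores(tr, ann, 1, ds$hierarchy)
  rows[[length(rows) + 1]] <- data.frame(
    lambda = lam, misassignment_rate = rate,
    gated_endothelial_f = fg$per_type$f_score[fg$per_type$type == "Endothelial cell"],
    zleiden_endothelial_f = fc$per_type$f_score[fc$per_type$type == "Endothelial cell"])
}
out <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.csv(out, "results/gating_spillover.csv", row.names = FALSE)
print(round(out, 3))
cat(sprintf("Misassignment grows from %.1f%% to %.1f%% across the sweep;\n",
            100 * out$misassignment_rate[1], 100 * max(out$misassignment_rate)))
cat(sprintf("endothelial F drops %.3f under gating vs %.3f under Z+Leiden profile annotation.\n",
            out$gated_endothelial_f[1] - out$gated_endothelial_f[nrow(out)],
            out$zleiden_endothelial_f[1] - out$zleiden_endothelial_f[nrow(out)]))
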