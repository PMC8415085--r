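# Hierarchical 2D gating: traversal semantics, partition property, and the
# spillover failure mode.

two_marker_table <- function(a, b) {
  cell_table(seq_along(a), 1, seq_along(a), 0,
             data.frame(A = a, B = b, check.names = FALSE))
}

# Gates in raw space for unit tests (identity treatment keeps coordinates
# legible).
raw_tree <- function(root) gating_tree(root, treatment = "raw")

test_that("a universal root gate labels everything and bounds are inclusive", {
  tab <- two_marker_table(c(-5, 0, 100), c(3, -2, 50))
  tree <- raw_tree(gating_level(
    list(gate("all", "A", "B", c(-Inf, Inf, -Inf, Inf), "All")), "None"))
  ann <- apply_gating_tree(tab, tree)
  expect_identical(ann$labels, rep("All", 3))
  expect_identical(ann$provenance$kind, "gated")
  # boundary-inclusive: point (6, 0) is inside x in [5,10], y in [-1,1]
  tab2 <- two_marker_table(c(6, 5, 10, 4.999), c(0, -1, 1, 0))
  tree2 <- raw_tree(gating_level(
    list(gate("g", "A", "B", c(5, 10, -1, 1), "In")), "Out"))
  expect_identical(apply_gating_tree(tab2, tree2)$labels,
                   c("In", "In", "In", "Out"))
})

test_that("cells descend a two-level tree in document order", {
  # cells at (A, B) = (2,0), (6,0), (6,5) under {A>5 -> {B>2 -> X, rest -> Y}, rest -> Z}
  tab <- two_marker_table(c(2, 6, 6), c(0, 0, 5))
  inner <- gating_level(list(gate("hi", "B", "A", c(2, Inf, -Inf, Inf), "X")),
                        "Y")
  tree <- raw_tree(gating_level(
    list(gate("right", "A", "B", c(5, Inf, -Inf, Inf), inner)), "Z"))
  expect_identical(apply_gating_tree(tab, tree)$labels, c("Z", "Y", "X"))
})

test_that("polygon gates use the even-odd rule", {
  diamond <- rbind(c(0, 2), c(2, 0), c(0, -2), c(-2, 0))
  tab <- two_marker_table(c(0, 1.5, 3), c(0, 1.4, 0))
  tree <- raw_tree(gating_level(
    list(gate("d", "A", "B", diamond, "In")), "Out"))
  expect_identical(apply_gating_tree(tab, tree)$labels,
                   c("In", "Out", "Out"))
})

test_that("gating partitions every cell exactly once and flags NAs", {
  ds <- build_default_scenario(400, seed = 1)
  ann <- apply_gating_tree(ds$cell_table, default_gating_tree())
  expect_equal(length(ann$labels), 400)
  expect_false(anyNA(ann$labels))
  expect_true(all(ann$labels %in% ds$hierarchy$levels[[1]]))
  tab <- ds$cell_table
  tab$CHGA[5] <- NA
  expect_warning(ann2 <- apply_gating_tree(tab, default_gating_tree()),
                 "ungated")
  expect_identical(ann2$labels[5], "ungated")
})

test_that("sibling order matters for overlapping gates", {
  tab <- two_marker_table(c(7), c(7))
  g1 <- gate("g1", "A", "B", c(5, Inf, -Inf, Inf), "P")
  g2 <- gate("g2", "B", "A", c(5, Inf, -Inf, Inf), "Q")
  t12 <- raw_tree(gating_level(list(g1, g2), "R"))
  t21 <- raw_tree(gating_level(list(g2, g1), "R"))
  expect_identical(apply_gating_tree(tab, t12)$labels, "P")
  expect_identical(apply_gating_tree(tab, t21)$labels, "Q")
})

test_that("gating is accurate without spillover and fails with it", {
  ds0 <- build_default_scenario(2500, seed = 5,
                                noise = noise_model(spillover_lambda = 0,
                                                    fold_region = NULL))
  rate0 <- spillover_misassignment_rate(ds0)
  expect_lt(rate0, 0.01)
  ds8 <- build_default_scenario(2500, seed = 5,
                                noise = noise_model(spillover_lambda = 0.8,
                                                    fold_region = NULL))
  expect_gt(spillover_misassignment_rate(ds8), rate0)
  # overall gating quality on clean data is high at coarse granularity
  f <- f_scores(truth_annotation(ds0),
                apply_gating_tree(ds0$cell_table, default_gating_tree()),
                level = 4, h = ds0$hierarchy)
  expect_gt(f$mean_f, 0.8)
})

test_that("a tree without an upstream cytokeratin gate is insensitive to spillover", {
  # endothelium gated directly on CD31/CD34: bleed no longer misroutes it
  direct <- gating_tree(gating_level(list(
    gate("vasc", "CD31", "CD34",
         c(0.3, Inf, -Inf, Inf), "Endothelial cell")
  ), "Fibroblast"), "arcsinh")
  rates <- vapply(c(0, 0.8), function(l) {
    ds <- build_default_scenario(1500, seed = 9,
                                 noise = noise_model(spillover_lambda = l,
                                                     fold_region = NULL))
    is_endo <- ds$truth == "Endothelial cell"
    ann <- apply_gating_tree(ds$cell_table, direct)
    mean(ann$labels[is_endo] != "Endothelial cell")
  }, 0)
  expect_lt(abs(rates[2] - rates[1]), 0.02)
})
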