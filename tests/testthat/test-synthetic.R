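# The synthetic tissue generator: determinism, abundances, intensity model,
# spillover and fold artifacts.

test_that("default scenario is deterministic and respects its contract", {
  ds1 <- build_default_scenario(600, seed = 7)
  ds2 <- build_default_scenario(600, seed = 7)
  expect_identical(ds1$cell_table, ds2$cell_table)
  expect_identical(ds1$truth, ds2$truth)
  expect_equal(nrow(ds1$cell_table), 600)
  expect_equal(length(ds1$truth), 600)
  expect_gte(length(marker_names(ds1$cell_table)), 20)
  expect_gte(length(unique(ds1$truth[ds1$truth != "Noise"])), 12)
  # every truth label resolves at all four levels
  for (lv in 1:4) {
    expect_false(anyNA(merge_to_level(ds1$truth, ds1$hierarchy, lv)))
  }
  # rare type present even at 600 cells
  expect_gte(sum(ds1$truth == "Neuroendocrine cell") +
               sum(ds1$noise_mask &
                     merge_to_level(ds1$truth, ds1$hierarchy, 1) == "Noise"), 1)
})

test_that("rare-type counts stay within binomial bounds and tiny n warns", {
  ds <- build_default_scenario(5000, seed = 7)
  n_rare <- sum(ds$truth == "Neuroendocrine cell") +
    sum(ds$noise_mask)  # a rare cell may fall in the fold region
  expect_gte(n_rare, 1)
  expect_lte(sum(ds$truth == "Neuroendocrine cell"), 60)
  expect_warning(build_default_scenario(100, seed = 1), "seeding one")
})

test_that("empirical abundances fall within 3 binomial standard errors", {
  n <- 4000
  ds <- build_default_scenario(n, seed = 3,
                               noise = noise_model(fold_region = NULL,
                                                   spillover_lambda = 0))
  ab <- vapply(ds$types, `[[`, 0, "abundance")
  names(ab) <- vapply(ds$types, `[[`, "", "name")
  for (tp in names(ab)) {
    if (n * ab[tp] < 5) next  # forced seeding perturbs the rarest types
    se <- sqrt(ab[tp] * (1 - ab[tp]) / n)
    expect_lt(abs(mean(ds$truth == tp) - ab[tp]), 3 * se + 1 / n, label = tp)
  }
})

test_that("intensity model follows exposure x (expression x signal + background)", {
  panel <- list(marker_spec("on", "lineage", 40, 10, 2, 1, exposure_scale = 2),
                marker_spec("off", "lineage", 40, 10, 0, 0, exposure_scale = 1))
  types <- list(cell_type_spec("T1", 1, list(on = 1), "stroma"))
  m <- simulate_intensities(types, panel, rep(1L, 10000), seed = 5)
  # unexpressed marker with zero background is exactly zero
  expect_true(all(m[, "off"] == 0))
  # doubling exposure doubles the column mean (Monte-Carlo tolerance)
  panel2 <- panel
  panel2[[1]]$exposure_scale <- 4
  m2 <- simulate_intensities(types, panel2, rep(1L, 10000), seed = 99)
  expect_lt(abs(mean(m2[, "on"]) / mean(m[, "on"]) - 2) / 2, 0.05)
  # identical expression gives indistinguishable distributions
  types2 <- list(cell_type_spec("A", 0.5, list(on = 1), "stroma"),
                 cell_type_spec("B", 0.5, list(on = 1), "stroma"))
  assign <- rep(1:2, each = 500)
  m3 <- simulate_intensities(types2, panel, assign, seed = 8)
  ks <- suppressWarnings(stats::ks.test(m3[assign == 1, "on"],
                                        m3[assign == 2, "on"]))
  expect_gt(ks$p.value, 0.01)
})

test_that("spillover adds the neighbour-mean bleed and nothing else", {
  tab <- tiny_table(x = c(0, 10, 500), y = c(0, 0, 0),
                    a = c(100, 0, 0), b = c(0, 0, 7))
  out <- inject_spillover(tab, noise_model(spillover_lambda = 0.5,
                                           spillover_radius = 20,
                                           fold_region = NULL))
  expect_equal(out$A[2], 0 + 0.5 * 100)  # B gains half of A's marker
  expect_equal(out$A[1], 100 + 0.5 * 0)
  expect_equal(out$B[3], 7)              # isolated cell unchanged
  # lambda = 0 is the identity
  expect_identical(inject_spillover(tab, noise_model(spillover_lambda = 0)),
                   tab)
  # spillover never decreases an intensity, never produces NaN
  ds <- build_default_scenario(500, seed = 2,
                               noise = noise_model(spillover_lambda = 0,
                                                   fold_region = NULL))
  before <- intensity_matrix(ds$cell_table)
  after <- inject_spillover(ds$cell_table, noise_model(spillover_lambda = 0.4))
  am <- intensity_matrix(after)
  expect_true(all(unclass(am) >= unclass(before) - 1e-12))
  expect_false(anyNA(unclass(am)))
  # cells in different regions never interact
  tab2 <- tiny_table(x = c(0, 5, 0), y = c(0, 0, 0), region = c(1, 1, 2),
                     a = c(100, 0, 0), b = c(0, 0, 0))
  out2 <- inject_spillover(tab2, noise_model(spillover_lambda = 1,
                                             spillover_radius = 50))
  expect_equal(out2$A[3], 0)
})

test_that("fold artifact masks the region and lifts every channel", {
  tab <- tiny_table(x = c(10, 900), y = c(10, 900), a = c(1, 2), b = c(3, 4))
  nm <- noise_model(fold_region = c(0, 100, 0, 100),
                    fold_offset_mean = 0, fold_offset_sd = 0)
  res <- inject_fold_artifact(tab, nm, seed = 1)
  expect_identical(res$table, tab)       # zero offset leaves values alone
  expect_identical(res$mask, c(TRUE, FALSE))
  # cell outside the region is untouched by a large offset
  nm2 <- noise_model(fold_region = c(0, 100, 0, 100),
                     fold_offset_mean = 50, fold_offset_sd = 5)
  res2 <- inject_fold_artifact(tab, nm2, seed = 1)
  expect_equal(unlist(res2$table[2, c("A", "B")]),
               unlist(tab[2, c("A", "B")]))
  expect_true(all(unlist(res2$table[1, c("A", "B")]) >
                    unlist(tab[1, c("A", "B")])))
  # empty region is a warned no-op
  nm3 <- noise_model(fold_region = c(2000, 2100, 0, 100))
  expect_warning(inject_fold_artifact(tab, nm3, seed = 1), "no cells")
})

test_that("fold cells separate from the bulk in per-cell mean intensity", {
  hits <- 0
  for (s in 1:8) {
    ds <- build_default_scenario(2000, seed = s)
    mm <- rowMeans(unclass(intensity_matrix(ds$cell_table)))
    q99 <- stats::quantile(mm[!ds$noise_mask], 0.99)
    if (all(mm[ds$noise_mask] > q99)) hits <- hits + 1
  }
  expect_gte(hits, 7)
})

test_that("datasets round-trip through the CSV/JSON writers", {
  ds <- suppressWarnings(build_default_scenario(150, seed = 4))
  dir <- tempfile()
  write_dataset(ds, dir)
  back <- read_cell_table(file.path(dir, "cells.csv"))
  expect_equal(nrow(back), 150)
  expect_identical(marker_names(back), marker_names(ds$cell_table))
  expect_equal(back$x, ds$cell_table$x, tolerance = 1e-9)
  h <- read_hierarchy(file.path(dir, "hierarchy.json"))
  expect_identical(hierarchy_level_counts(h),
                   hierarchy_level_counts(ds$hierarchy))
  unlink(dir, recursive = TRUE)
})
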