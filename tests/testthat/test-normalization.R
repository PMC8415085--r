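# The five data treatments: closed forms, degenerate inputs, invariants.

mat <- function(v, markers = NULL) {
  m <- as.matrix(v)
  if (is.null(markers)) markers <- paste0("m", seq_len(ncol(m)))
  colnames(m) <- markers
  m
}

test_that("Z normalization centres and scales with population sd", {
  out <- normalize_z(mat(c(1, 2, 3)))
  expect_equal(as.numeric(out), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-4)
  # idempotent on an already-standard column
  zed <- mat(as.numeric(scale(c(4, 8, 15, 16))) * sqrt(4 / 3))
  expect_equal(unclass(normalize_z(zed)), unclass(zed), tolerance = 1e-12,
               ignore_attr = TRUE)
  # constant columns obey the zero-variance policy
  expect_equal(as.numeric(normalize_z(mat(c(5, 5, 5)))), c(0, 0, 0))
  expect_error(normalize_z(mat(c(5, 5, 5)),
                           normalization_config(zero_variance_policy = "error")),
               "zero-variance")
  expect_error(normalize_z(mat(1)), "at least 2 cells")
})

test_that("Z output columns have mean 0 and unit population sd", {
  set.seed(42)
  x <- matrix(rexp(600), 100, 6, dimnames = list(NULL, paste0("m", 1:6)))
  out <- unclass(normalize_z(x))
  expect_true(all(abs(colMeans(out)) < 1e-9))
  expect_true(all(abs(sqrt(colMeans(out^2)) - 1) < 1e-9))
})

test_that("log double-Z matches its definition step by step", {
  x <- matrix(c(10, 0, 0, 0, 10, 0, 0, 0, 10), 3, 3, byrow = TRUE,
              dimnames = list(NULL, c("a", "b", "c")))
  # independent step-by-step oracle
  z1 <- apply(x, 2, function(col) (col - mean(col)) / sqrt(mean((col - mean(col))^2)))
  z2 <- t(apply(z1, 1, function(row) (row - mean(row)) / sqrt(mean((row - mean(row))^2))))
  expected <- -log(1 - pmin(pnorm(z2), 1 - 1e-12))
  out <- normalize_log_double_z(x)
  expect_equal(unclass(out), expected, ignore_attr = TRUE, tolerance = 1e-12)
  # an entry whose cell-wise z is exactly 0 maps to ln 2
  y <- cbind(a = c(1, 0, 0), b = c(-1, 0, 0), c = c(5, 5, 5))
  expect_equal(unname(unclass(normalize_log_double_z(y))[1, 3]), log(2),
               tolerance = 1e-12)
})

test_that("log double-Z clips probabilities so outputs stay finite", {
  # cell 1 is the lone positive for marker 1 and flat elsewhere, so its
  # cell-wise z there is sqrt(59) ~ 7.7, beyond the clipping point
  set.seed(1)
  v <- rnorm(59)
  x <- cbind(m1 = c(100, rep(0, 59)),
             matrix(rep(c(0, v), 59), 60, 59,
                    dimnames = list(NULL, paste0("m", 2:60))))
  out <- unclass(normalize_log_double_z(x))
  expect_true(all(is.finite(out)))
  expect_equal(max(out), -log(1e-12), tolerance = 1e-6)
  # cells with a constant marker profile map to ln 2 across the row
  y <- matrix(c(1, 1, 2, 2, 3, 3), 3, 2, byrow = TRUE,
              dimnames = list(NULL, c("a", "b")))
  outy <- unclass(normalize_log_double_z(y))
  expect_true(all(abs(outy - log(2)) < 1e-12))
})

test_that("min-max caps at the 1st/99th percentiles and rescales to [0,1]", {
  x <- mat(0:100)
  out <- unclass(normalize_minmax(x))
  expect_equal(out[51], (50 - 1) / 98, tolerance = 1e-12)
  expect_equal(out[1], 0)    # below the 1st percentile clips to 0
  expect_equal(out[101], 1)  # above the 99th percentile clips to 1
  expect_true(all(out >= 0 & out <= 1))
  # order preserved within the clipped range
  expect_true(all(diff(out) >= 0))
  expect_warning(normalize_minmax(mat(rep(3, 10))), "degenerate")
})

test_that("arcsinh is the odd closed form with cofactor 150", {
  x <- mat(c(0, 150, -150, 15))
  out <- as.numeric(normalize_arcsinh(x))
  expect_equal(out[1], 0)
  expect_equal(out[2], asinh(1), tolerance = 1e-12)
  expect_equal(out[3], -asinh(1), tolerance = 1e-12)
  # linear regime: asinh(x/150) ~ x/150 within 0.5% for |x| <= 15
  xs <- seq(-15, 15, by = 0.5); xs <- xs[xs != 0]
  rel <- abs(asinh(xs / 150) - xs / 150) / abs(xs / 150)
  expect_true(all(rel < 0.005))
  expect_error(normalize_arcsinh(x, normalization_config(arcsinh_cofactor = -1)),
               "positive")
})

test_that("apply_treatment dispatches and rejects unknown names", {
  x <- mat(cbind(c(1, 2, 3), c(0, 5, 10)), c("a", "b"))
  expect_identical(unclass(apply_treatment(x, "raw")), unclass(x),
                   ignore_attr = TRUE)
  expect_equal(unclass(apply_treatment(x, "z")), unclass(normalize_z(x)))
  mm <- unclass(apply_treatment(x, "minmax"))
  expect_true(all(mm >= 0 & mm <= 1))
  expect_error(apply_treatment(x, "quantile"), "valid treatments")
})

test_that("all treatments are permutation-equivariant over cells and NaN-free", {
  set.seed(7)
  x <- matrix(rnorm(400, 10, 20), 50, 8,
              dimnames = list(NULL, paste0("m", 1:8)))
  perm <- sample(50)
  for (tr in all_treatments()) {
    a <- unclass(apply_treatment(x, tr))
    b <- unclass(apply_treatment(x[perm, ], tr))
    expect_equal(a[perm, ], b, ignore_attr = TRUE, tolerance = 1e-12,
                 label = tr)
    expect_false(any(is.na(a) | is.infinite(a)), label = tr)
    expect_identical(dim(a), dim(x), label = tr)
  }
})
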