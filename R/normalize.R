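# Single-cell intensity treatments. Each treatment maps a cells-by-markers
# intensity matrix to a matrix of identical shape; all are applied per
# dataset (no per-tile or per-batch correction).

TREATMENTS <- c("raw", "z", "log_double_z", "minmax", "arcsinh")

#' Normalization configuration
#'
#' @param arcsinh_cofactor divisor applied before the arcsinh; default 150,
#'   the standard cofactor for fluorescence-scale CODEX intensities.
#' @param minmax_low_pct,minmax_high_pct capping percentiles for min-max
#'   (defaults 1 and 99; the upper cap removes artificially high background).
#' @param probability_epsilon probabilities in the log double-Z treatment are
#'   clipped to at most `1 - probability_epsilon` so the negative log stays
#'   finite.
#' @param zero_variance_policy "zeros" maps constant columns (or rows, for the
#'   cell-wise Z) to zeros; "error" aborts instead.
#' @return a `normalization_config` list.
#' @export
normalization_config <- function(arcsinh_cofactor = 150,
                                 minmax_low_pct = 1,
                                 minmax_high_pct = 99,
                                 probability_epsilon = 1e-12,
                                 zero_variance_policy = c("zeros", "error")) {
  zero_variance_policy <- match.arg(zero_variance_policy)
  stop_if_not(arcsinh_cofactor > 0, "arcsinh_cofactor must be positive")
  stop_if_not(minmax_low_pct < minmax_high_pct,
              "minmax_low_pct must be below minmax_high_pct")
  stop_if_not(probability_epsilon > 0 && probability_epsilon < 0.5,
              "probability_epsilon must lie in (0, 0.5)")
  structure(list(arcsinh_cofactor = arcsinh_cofactor,
                 minmax_low_pct = minmax_low_pct,
                 minmax_high_pct = minmax_high_pct,
                 probability_epsilon = probability_epsilon,
                 zero_variance_policy = zero_variance_policy),
            class = "normalization_config")
}

as_im <- function(values, template, treatment) {
  dimnames(values) <- dimnames(template)
  attr(values, "treatment") <- treatment
  class(values) <- c("intensity_matrix", "matrix", "array")
  values
}

# Column-wise Z with population sd; constant columns per policy.
z_columns <- function(m, policy) {
  mu <- colMeans(m)
  sd <- col_pop_sd(m)
  const <- sd <= 0
  if (any(const) && policy == "error") {
    stop("zero-variance marker column(s): ",
         paste(colnames(m)[const], collapse = ", "), call. = FALSE)
  }
  sd[const] <- 1
  out <- sweep(sweep(m, 2, mu, "-"), 2, sd, "/")
  out[, const] <- 0
  out
}

#' Z normalization (per marker)
#'
#' Each marker column is centred and scaled to unit population variance
#' across all cells, equalizing channels whose raw scales differ with
#' antibody staining strength and exposure time.
#'
#' @param m an `intensity_matrix`.
#' @param cfg a [normalization_config()].
#' @return treated `intensity_matrix` (treatment "z").
#' @export
normalize_z <- function(m, cfg = normalization_config()) {
  stop_if_not(nrow(m) >= 2, "Z normalization needs at least 2 cells")
  as_im(z_columns(unclass(m), cfg$zero_variance_policy), m, "z")
}

#' Log double-Z normalization
#'
#' Marker-wise Z, then a second Z across markers within each cell, then the
#' cell-wise Z scores are turned into upper-tail probabilities via the
#' standard normal CDF and amplified with a negative log of the complement:
#' `-log(1 - pnorm(z2))`. Because a cell is positive for only a handful of
#' markers, the within-cell Z isolates its positive channels with high
#' probability, and the negative log stretches probabilities near one.
#'
#' @inheritParams normalize_z
#' @return treated `intensity_matrix` (treatment "log_double_z").
#' @export
normalize_log_double_z <- function(m, cfg = normalization_config()) {
  stop_if_not(nrow(m) >= 2, "log double-Z needs at least 2 cells")
  stop_if_not(ncol(m) >= 2, "log double-Z needs at least 2 markers")
  z1 <- z_columns(unclass(m), cfg$zero_variance_policy)
  mu <- rowMeans(z1)
  sd <- sqrt(rowMeans(z1^2) - mu^2)
  const <- sd <= 0
  if (any(const) && cfg$zero_variance_policy == "error") {
    stop("cell(s) with constant marker profile after Z", call. = FALSE)
  }
  sd[const] <- 1
  z2 <- (z1 - mu) / sd
  z2[const, ] <- 0
  p <- stats::pnorm(z2)
  p <- pmin(p, 1 - cfg$probability_epsilon)
  as_im(-log(1 - p), m, "log_double_z")
}

#' Percentile-capped min-max normalization
#'
#' Per marker, values are clipped to the 1st and 99th percentiles (linear
#' interpolation between order statistics) and rescaled to `[0, 1]`. The
#' upper cap discards artificially high background intensities.
#'
#' @inheritParams normalize_z
#' @return treated `intensity_matrix` (treatment "minmax"), values in [0, 1].
#' @export
normalize_minmax <- function(m, cfg = normalization_config()) {
  v <- unclass(m)
  lo <- apply(v, 2, stats::quantile, probs = cfg$minmax_low_pct / 100,
              names = FALSE, type = 7)
  hi <- apply(v, 2, stats::quantile, probs = cfg$minmax_high_pct / 100,
              names = FALSE, type = 7)
  out <- v
  for (j in seq_len(ncol(v))) {
    if (hi[j] <= lo[j]) {
      warning("degenerate percentile range in column '", colnames(v)[j],
              "'; column set to zeros")
      out[, j] <- 0
    } else {
      out[, j] <- (pmin(pmax(v[, j], lo[j]), hi[j]) - lo[j]) / (hi[j] - lo[j])
    }
  }
  as_im(out, m, "minmax")
}

#' Arcsinh normalization
#'
#' `asinh(x / cofactor)` elementwise with cofactor 150 by default.
#' Well-defined for the low or negative values that arise from background
#' subtraction; approximately linear for `|x|` well below the cofactor and
#' logarithmic far above it.
#'
#' @inheritParams normalize_z
#' @return treated `intensity_matrix` (treatment "arcsinh").
#' @export
normalize_arcsinh <- function(m, cfg = normalization_config()) {
  stop_if_not(cfg$arcsinh_cofactor > 0, "cofactor must be positive")
  as_im(asinh(unclass(m) / cfg$arcsinh_cofactor), m, "arcsinh")
}

#' Apply a named treatment
#'
#' Dispatches to one of the five treatments compared by the benchmark;
#' "raw" is the identity.
#'
#' @param m an `intensity_matrix`.
#' @param name one of `"raw"`, `"z"`, `"log_double_z"`, `"minmax"`,
#'   `"arcsinh"`.
#' @param cfg a [normalization_config()].
#' @return treated `intensity_matrix`.
#' @export
apply_treatment <- function(m, name, cfg = normalization_config()) {
  if (!name %in% TREATMENTS) {
    stop("unknown treatment '", name, "'; valid treatments: ",
         paste(TREATMENTS, collapse = ", "), call. = FALSE)
  }
  switch(name,
         raw = as_im(unclass(m), m, "raw"),
         z = normalize_z(m, cfg),
         log_double_z = normalize_log_double_z(m, cfg),
         minmax = normalize_minmax(m, cfg),
         arcsinh = normalize_arcsinh(m, cfg))
}

#' The five treatments in benchmark order
#' @return character vector.
#' @export
all_treatments <- function() TREATMENTS
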