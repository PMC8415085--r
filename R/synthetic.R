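# Synthetic CODEX-like tissue generator. Produces segmented single-cell
# quantification tables with known ground truth, emulating the noise modes
# that confound cell-type calling in multiplexed imaging: low-signal
# channels, high-background channels, per-channel exposure differences,
# lateral segmentation spillover between adjacent cells, and an
# all-marker-positive folded-tissue region.

#' Marker channel specification
#'
#' @param name marker name.
#' @param kind "lineage" (identity-discriminating) or "phenotypic"
#'   (continuous activation state).
#' @param signal_mean,signal_sd mean and sd of the positive-signal lognormal,
#'   on the natural fluorescence scale.
#' @param background_mean,background_sd Gaussian background (may drive values
#'   negative, as after background subtraction).
#' @param exposure_scale per-channel multiplier emulating antibody staining
#'   strength and exposure-time differences between channels.
#' @return a `marker_spec` list.
#' @export
marker_spec <- function(name, kind = c("lineage", "phenotypic"),
                        signal_mean, signal_sd,
                        background_mean = 0, background_sd = 0,
                        exposure_scale = 1) {
  kind <- match.arg(kind)
  stop_if_not(signal_mean > 0 && signal_sd > 0, "signal parameters must be positive")
  stop_if_not(background_mean >= 0 && background_sd >= 0,
              "background parameters must be nonnegative")
  stop_if_not(exposure_scale > 0, "exposure_scale must be positive")
  structure(list(name = name, kind = kind,
                 signal_mean = signal_mean, signal_sd = signal_sd,
                 background_mean = background_mean,
                 background_sd = background_sd,
                 exposure_scale = exposure_scale),
            class = "marker_spec")
}

#' Cell type specification
#'
#' @param name type name (level-1 vocabulary).
#' @param abundance expected population fraction in (0, 1].
#' @param expression named list: marker -> expression level in `[0, 1]`
#'   (fraction of the marker's signal mean), or a length-2 band `c(lo, hi)`
#'   from which each cell draws uniformly (phenotypic continuum). Markers not
#'   listed are background-only.
#' @param compartment spatial compartment ("epithelium", "vasculature",
#'   "stroma" or "muscle").
#' @return a `cell_type_spec` list.
#' @export
cell_type_spec <- function(name, abundance, expression, compartment) {
  stop_if_not(abundance > 0 && abundance <= 1, "abundance must lie in (0, 1]")
  for (v in expression) {
    stop_if_not(all(v >= 0 & v <= 1) && length(v) %in% 1:2,
                "expression levels must be scalars or bands in [0, 1]")
  }
  structure(list(name = name, abundance = abundance,
                 expression = expression, compartment = compartment),
            class = "cell_type_spec")
}

#' Noise model for spillover and tissue-fold artifacts
#'
#' @param spillover_lambda fraction of the mean adjacent-cell signal added to
#'   each cell per channel (segmentation bleed), in `[0, 1]`.
#' @param spillover_radius neighbour radius in tissue units.
#' @param fold_region optional `c(x_min, x_max, y_min, y_max)` rectangle; all
#'   channels of cells inside it receive a nonnegative additive offset and
#'   the cells' truth label becomes "Noise".
#' @param fold_offset_mean,fold_offset_sd parameters of the
#'   truncated-at-zero Gaussian fold offset. The draw is multiplied by each
#'   channel's reference scale (see [inject_fold_artifact()]); with the
#'   default per-channel scales of the full scenario, a mean of 1 makes a
#'   fold cell read like a typical positive on every channel — the
#'   "positive for all markers" artifact — while respecting each channel's
#'   exposure, so low-exposure channels read proportionally low.
#' @param fold_regions restrict the fold artifact to these region ids
#'   (default: first region only).
#' @return a `noise_model` list.
#' @export
noise_model <- function(spillover_lambda = 0.3, spillover_radius = 20,
                        fold_region = c(60, 240, 720, 920),
                        fold_offset_mean = 1.0, fold_offset_sd = 0.3,
                        fold_regions = 1L) {
  stop_if_not(spillover_lambda >= 0 && spillover_lambda <= 1,
              "spillover_lambda must lie in [0, 1]")
  stop_if_not(spillover_radius > 0, "spillover_radius must be positive")
  if (!is.null(fold_region)) {
    stop_if_not(length(fold_region) == 4 &&
                  fold_region[1] < fold_region[2] &&
                  fold_region[3] < fold_region[4],
                "fold_region must be c(x_min, x_max, y_min, y_max)")
  }
  stop_if_not(fold_offset_mean >= 0 && fold_offset_sd >= 0,
              "fold offsets must be nonnegative")
  structure(list(spillover_lambda = spillover_lambda,
                 spillover_radius = spillover_radius,
                 fold_region = fold_region,
                 fold_offset_mean = fold_offset_mean,
                 fold_offset_sd = fold_offset_sd,
                 fold_regions = fold_regions),
            class = "noise_model")
}

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "codexbench")
  if (!nzchar(p)) {
    # during development before installation
    p <- file.path("inst", "extdata", file)
  }
  stop_if_not(file.exists(p), paste("fixture not found:", file))
  p
}

#' Default marker panel
#'
#' 22-channel colon-style panel loaded from the versioned fixture file:
#' epithelial, immune, stromal, vascular and muscle lineage markers plus the
#' phenotypic CD69/CD127 continuum pair; CHGA is a deliberately low-signal
#' channel and CD15/CD16 carry high background.
#'
#' @return list of [marker_spec()] objects.
#' @export
default_panel <- function() {
  raw <- jsonlite::read_json(fixture_path("synthetic_panel.json"))
  lapply(raw$markers, function(m) {
    marker_spec(m$name, m$kind, m$signal_mean, m$signal_sd,
                m$background_mean, m$background_sd, m$exposure_scale)
  })
}

#' Default cell-type roster
#'
#' 16 types across four compartments, including a 0.3% neuroendocrine-like
#' rare type marked solely by the low-signal CHGA channel, a 0.3%
#' neutrophil-like type marked by the high-background CD15/CD16 pair, a CD4
#' T-cell pair split only by the CD69/CD127 phenotypic continuum, and a
#' CD31/CD34-high vascular compartment adjacent to the cytokeratin-high
#' epithelium.
#'
#' @return list of [cell_type_spec()] objects.
#' @export
default_cell_types <- function() {
  raw <- jsonlite::read_json(fixture_path("synthetic_panel.json"))
  lapply(raw$cell_types, function(ct) {
    expr <- lapply(ct$expression, function(v) unlist(v))
    cell_type_spec(ct$name, ct$abundance, expr, ct$compartment)
  })
}

#' Simulate noise-free marker intensities
#'
#' For cell i and marker m the quantified intensity is
#' `exposure_m * (expression(type_i, m) * S + B)` with `S` lognormal with
#' mean `signal_mean_m` and sd `signal_sd_m` and `B` Gaussian background
#' `N(background_mean_m, background_sd_m)` (so values can be negative, as
#' after background subtraction). Band-valued expression levels are drawn
#' uniformly per cell within the band.
#'
#' @param types list of [cell_type_spec()].
#' @param panel list of [marker_spec()].
#' @param assignments integer vector of type indices, one per cell.
#' @param seed integer seed.
#' @return `intensity_matrix` (treatment "raw") of dim cells x markers.
#' @export
simulate_intensities <- function(types, panel, assignments, seed) {
  stop_if_not(all(assignments >= 1 & assignments <= length(types)),
              "every assignment must index a type")
  n <- length(assignments)
  p <- length(panel)
  mnames <- vapply(panel, `[[`, "", "name")
  with_local_seed(seed, {
    out <- matrix(0, n, p, dimnames = list(NULL, mnames))
    for (j in seq_len(p)) {
      mk <- panel[[j]]
      expr <- numeric(n)
      for (ti in seq_along(types)) {
        rows <- which(assignments == ti)
        if (length(rows) == 0) next
        lv <- types[[ti]]$expression[[mk$name]]
        if (is.null(lv)) {
          expr[rows] <- 0
        } else if (length(lv) == 2) {
          expr[rows] <- stats::runif(length(rows), lv[1], lv[2])
        } else {
          expr[rows] <- lv
        }
      }
      # lognormal parameterised by natural-scale mean and sd
      cv2 <- (mk$signal_sd / mk$signal_mean)^2
      sdlog <- sqrt(log(1 + cv2))
      meanlog <- log(mk$signal_mean) - sdlog^2 / 2
      sig <- stats::rlnorm(n, meanlog, sdlog)
      bkg <- if (mk$background_sd > 0) {
        stats::rnorm(n, mk$background_mean, mk$background_sd)
      } else {
        rep(mk$background_mean, n)
      }
      out[, j] <- mk$exposure_scale * (expr * sig + bkg)
    }
    attr(out, "treatment") <- "raw"
    class(out) <- c("intensity_matrix", "matrix", "array")
    out
  })
}

#' Add lateral segmentation spillover
#'
#' Each cell gains `spillover_lambda` times the mean intensity of its
#' neighbours within `spillover_radius` (Euclidean distance in x,y, within
#' the same tissue region, excluding itself), per channel — an additive
#' bleed-in, as when a neighbour's cytoplasmic stain is quantified inside an
#' adjacent cell's segmentation mask. Cells with no neighbour in radius are
#' unchanged; the input table is not mutated.
#'
#' @param table a `cell_table`.
#' @param model a [noise_model()].
#' @return new `cell_table` with spillover applied.
#' @export
inject_spillover <- function(table, model) {
  stop_if_not(model$spillover_lambda >= 0, "spillover_lambda must be nonnegative")
  if (model$spillover_lambda == 0) return(table)
  mk <- marker_names(table)
  vals <- as.matrix(table[, mk, drop = FALSE])
  out <- vals
  r2 <- model$spillover_radius^2
  for (reg in unique(table$region)) {
    rows <- which(table$region == reg)
    if (length(rows) < 2) next
    xy <- cbind(table$x[rows], table$y[rows])
    nr <- length(rows)
    chunk <- 1024L
    for (s in seq(1L, nr, by = chunk)) {
      e <- min(s + chunk - 1L, nr)
      blk <- s:e
      d2 <- outer(rowSums(xy[blk, , drop = FALSE]^2), rowSums(xy^2), "+") -
        2 * tcrossprod(xy[blk, , drop = FALSE], xy)
      for (i in seq_along(blk)) {
        nb <- which(d2[i, ] <= r2)
        nb <- nb[nb != blk[i]]
        if (length(nb) == 0) next
        gi <- rows[blk[i]]
        # bleed-in is physical signal: a negative neighbour mean (pure
        # background noise) contributes nothing
        out[gi, ] <- vals[gi, ] +
          model$spillover_lambda *
            pmax(0, colMeans(vals[rows[nb], , drop = FALSE]))
      }
    }
  }
  set_intensities(table, out)
}

#' Add a tissue-fold artifact
#'
#' Every cell inside `fold_region` (in the configured regions) receives an
#' independent nonnegative additive offset on every channel, drawn from a
#' Gaussian truncated at zero and multiplied by that channel's reference
#' scale — emulating a physically folded tissue area where every channel
#' reads like a positive stain. The extra fluorescence of folded tissue
#' passes through the same per-channel exposure and gain as real signal, so
#' the offset scales with each channel rather than being one absolute
#' magnitude; `channel_scales = NULL` (all 1) reduces to a shared absolute
#' offset. Affected cells are flagged in the returned mask; their truth
#' label should become "Noise".
#'
#' @param table a `cell_table`.
#' @param model a [noise_model()]; `fold_region` must be set.
#' @param seed integer seed.
#' @param channel_scales optional named vector of per-channel reference
#'   scales (e.g. exposure x signal mean); default all 1.
#' @return list with elements `table` (new `cell_table`) and `mask`
#'   (logical, TRUE for fold-region cells).
#' @export
inject_fold_artifact <- function(table, model, seed = 0L,
                                 channel_scales = NULL) {
  mask <- rep(FALSE, nrow(table))
  if (is.null(model$fold_region)) {
    warning("no fold_region set; fold artifact is a no-op")
    return(list(table = table, mask = mask))
  }
  fr <- model$fold_region
  inside <- table$x >= fr[1] & table$x <= fr[2] &
    table$y >= fr[3] & table$y <= fr[4] &
    table$region %in% model$fold_regions
  mask[inside] <- TRUE
  if (!any(mask)) {
    warning("fold_region contains no cells; fold artifact is a no-op")
    return(list(table = table, mask = mask))
  }
  mk <- marker_names(table)
  vals <- as.matrix(table[, mk, drop = FALSE])
  if (is.null(channel_scales)) {
    channel_scales <- stats::setNames(rep(1, length(mk)), mk)
  }
  stop_if_not(all(mk %in% names(channel_scales)),
              "channel_scales must cover every marker")
  k <- sum(mask) * length(mk)
  offs <- with_local_seed(seed, {
    if (model$fold_offset_sd == 0) {
      rep(model$fold_offset_mean, k)
    } else {
      # inverse-CDF draw from N(mean, sd) truncated below at 0
      lo <- stats::pnorm(0, model$fold_offset_mean, model$fold_offset_sd)
      stats::qnorm(stats::runif(k, lo, 1),
                   model$fold_offset_mean, model$fold_offset_sd)
    }
  })
  offm <- sweep(matrix(offs, nrow = sum(mask)), 2, channel_scales[mk], "*")
  vals[mask, ] <- vals[mask, ] + offm
  list(table = set_intensities(table, vals), mask = mask)
}

compartment_bands <- list(
  epithelium = c(0, 340),
  vasculature = c(340, 420),
  stroma = c(420, 800),
  muscle = c(800, 1000)
)

#' Generate the default synthetic colon scenario
#'
#' Builds a complete benchmark dataset: multinomial draw of cell types (the
#' rarest type is force-seeded with at least one cell), spatial placement in
#' four compartment bands per region inside a `[0, 1000]^2` tissue box,
#' noise-free intensity simulation, segmentation spillover, and a fold
#' artifact in region 1 whose cells are relabelled "Noise".
#'
#' @param n_cells total number of cells (>= 100).
#' @param seed integer seed; the full dataset is a deterministic function of
#'   `(n_cells, seed, noise, n_regions)`.
#' @param noise a [noise_model()].
#' @param n_regions number of separate tissue regions.
#' @return a `synthetic_dataset`: list with `cell_table`, `truth` (level-1
#'   labels incl. "Noise"), `noise_mask`, `hierarchy`, `types`, `panel` and
#'   `config`.
#' @export
build_default_scenario <- function(n_cells, seed,
                                   noise = noise_model(),
                                   n_regions = 2L) {
  stop_if_not(n_cells >= 100, "n_cells must be at least 100")
  types <- default_cell_types()
  panel <- default_panel()
  ab <- vapply(types, `[[`, 0, "abundance")
  stop_if_not(abs(sum(ab) - 1) < 1e-9, "type abundances must sum to 1")
  tnames <- vapply(types, `[[`, "", "name")

  assign_seed <- seed
  dat <- with_local_seed(assign_seed, {
    assignments <- sample.int(length(types), n_cells, replace = TRUE, prob = ab)
    rarest <- which.min(ab)
    if (n_cells * ab[rarest] < 1) {
      warning("n_cells too small to expect any '", tnames[rarest],
              "' cell; seeding one")
    }
    if (sum(assignments == rarest) == 0) {
      assignments[sample.int(n_cells, 1)] <- rarest
    }
    region <- sample(rep_len(seq_len(n_regions), n_cells))
    comp <- vapply(types, `[[`, "", "compartment")[assignments]
    x <- numeric(n_cells)
    y <- stats::runif(n_cells, 0, 1000)
    for (cp in names(compartment_bands)) {
      rows <- comp == cp
      b <- compartment_bands[[cp]]
      x[rows] <- stats::runif(sum(rows), b[1], b[2])
    }
    list(assignments = assignments, region = region, x = x, y = y)
  })

  im <- simulate_intensities(types, panel, dat$assignments, seed = seed + 1L)
  tab <- cell_table(seq_len(n_cells), dat$region, dat$x, dat$y, unclass(im))
  tab <- inject_spillover(tab, noise)
  if (is.null(noise$fold_region)) {
    fold <- list(table = tab, mask = rep(FALSE, n_cells))
  } else {
    scales <- vapply(panel, function(mk) mk$exposure_scale * mk$signal_mean, 0)
    names(scales) <- vapply(panel, `[[`, "", "name")
    fold <- inject_fold_artifact(tab, noise, seed = seed + 2L,
                                 channel_scales = scales)
  }
  truth <- tnames[dat$assignments]
  truth[fold$mask] <- "Noise"

  structure(list(
    cell_table = fold$table,
    truth = truth,
    noise_mask = fold$mask,
    hierarchy = synthetic_hierarchy(),
    types = types,
    panel = panel,
    config = list(n_cells = n_cells, seed = seed, n_regions = n_regions,
                  noise = unclass(noise))
  ), class = "synthetic_dataset")
}

#' Expected noise-free type-by-marker profile matrix
#'
#' Midpoints of band-valued expression levels; used as the reference for
#' profile-correlation annotation.
#'
#' @param types list of [cell_type_spec()].
#' @param panel list of [marker_spec()].
#' @return numeric matrix, types x markers, rownames = type names.
#' @export
expected_profiles <- function(types = default_cell_types(),
                              panel = default_panel()) {
  mnames <- vapply(panel, `[[`, "", "name")
  out <- matrix(0, length(types), length(mnames),
                dimnames = list(vapply(types, `[[`, "", "name"), mnames))
  for (ti in seq_along(types)) {
    for (m in names(types[[ti]]$expression)) {
      out[ti, m] <- mean(types[[ti]]$expression[[m]])
    }
  }
  out
}

#' Write a synthetic dataset to disk
#'
#' Emits cells.csv (cell table), truth.csv (cell_id, label), config.json and
#' hierarchy.json under `dir`.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cell_table(dataset$cell_table, file.path(dir, "cells.csv"))
  utils::write.csv(data.frame(cell_id = dataset$cell_table$cell_id,
                              label = dataset$truth),
                   file.path(dir, "truth.csv"), row.names = FALSE)
  jsonlite::write_json(dataset$config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_hierarchy(dataset$hierarchy, file.path(dir, "hierarchy.json"))
  invisible(dir)
}
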