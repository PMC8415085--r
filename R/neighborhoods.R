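# Cellular neighborhood analysis: per-cell spatial kNN window composition
# vectors, clustered into recurrent neighborhoods, named by the cell types
# enriched relative to the tissue as a whole; plus detection of the
# noise neighborhood produced by a tissue fold.

#' Per-cell spatial window composition
#'
#' Each cell's window is itself plus its `window_size - 1` nearest
#' neighbours by Euclidean (x, y) distance within the same tissue region;
#' each row gives the fraction of every annotated type in that window (rows
#' sum to 1).
#'
#' @param table a `cell_table`.
#' @param ann an `annotation_set` over the same cells.
#' @param window_size cells per window, including the index cell.
#' @return a `window_matrix`: cells x types matrix with `window_size`
#'   attribute.
#' @export
compute_windows <- function(table, ann, window_size = 10L) {
  stop_if_not(length(ann$labels) == nrow(table),
              "annotation must cover the table's cells")
  stop_if_not(window_size >= 1, "window_size must be positive")
  types <- sort(unique(ann$labels))
  out <- matrix(0, nrow(table), length(types),
                dimnames = list(NULL, types))
  for (reg in unique(table$region)) {
    rows <- which(table$region == reg)
    if (length(rows) < window_size) {
      stop("region '", reg, "' has fewer cells (", length(rows),
           ") than window_size", call. = FALSE)
    }
    lab <- factor(ann$labels[rows], levels = types)
    if (window_size == 1) {
      for (i in seq_along(rows)) out[rows[i], lab[i]] <- 1
      next
    }
    xy <- cbind(table$x[rows], table$y[rows])
    nn <- knn_brute(xy, window_size - 1L, "euclidean")
    for (i in seq_along(rows)) {
      members <- c(i, nn$index[i, ])
      tab <- tabulate(lab[members], nbins = length(types))
      out[rows[i], ] <- tab / window_size
    }
  }
  attr(out, "window_size") <- window_size
  class(out) <- c("window_matrix", "matrix", "array")
  out
}

#' Cluster windows into cellular neighborhoods
#'
#' k-means on the window composition rows. Each neighborhood's enrichment
#' for a type is its within-neighborhood frequency divided by the overall
#' tissue frequency; neighborhoods are named by their top two enriched
#' types (ties lexicographic).
#'
#' @param w a `window_matrix` from [compute_windows()].
#' @param ann the `annotation_set` the windows were computed from.
#' @param n_neighborhoods number of neighborhoods (>= 2).
#' @param seed integer seed.
#' @return a `neighborhood_assignment`: list with `labels` (per-cell
#'   neighborhood id), `n_neighborhoods`, `enrichment` (neighborhoods x
#'   types), `names`.
#' @export
cluster_windows <- function(w, ann, n_neighborhoods, seed = 0L) {
  stop_if_not(n_neighborhoods >= 2, "need at least 2 neighborhoods")
  ca <- cluster_kmeans(unclass(w), k = n_neighborhoods, seed = seed)
  types <- colnames(w)
  overall <- as.numeric(table(factor(ann$labels, levels = types))) /
    length(ann$labels)
  enr <- matrix(0, n_neighborhoods, length(types),
                dimnames = list(NULL, types))
  nms <- character(n_neighborhoods)
  for (nb in seq_len(n_neighborhoods)) {
    members <- ca$labels == nb
    freq <- as.numeric(table(factor(ann$labels[members], levels = types))) /
      sum(members)
    e <- ifelse(overall > 0, freq / overall, 0)
    enr[nb, ] <- e
    ord <- order(-e, types)
    nms[nb] <- paste(types[ord[seq_len(min(2, length(types)))]],
                     collapse = " / ")
  }
  structure(list(labels = ca$labels, n_neighborhoods = n_neighborhoods,
                 enrichment = enr, names = nms),
            class = "neighborhood_assignment")
}

#' Is the fold-noise neighborhood detected?
#'
#' TRUE iff some neighborhood contains at least `min_share` of the
#' fold-masked cells and the masked cells are the plurality truth label
#' within that neighborhood (when `truth_labels` is supplied; otherwise the
#' masked cells must outnumber every other label, i.e. exceed half of the
#' neighborhood).
#'
#' @param na a `neighborhood_assignment`.
#' @param truth_mask logical vector marking fold-region cells.
#' @param truth_labels optional character truth labels for the plurality
#'   check.
#' @param min_share minimum fraction of masked cells captured by one
#'   neighborhood.
#' @return logical scalar.
#' @export
noise_neighborhood_detected <- function(na, truth_mask, truth_labels = NULL,
                                        min_share = 0.5) {
  stop_if_not(any(truth_mask), "truth_mask marks no cells")
  for (nb in seq_len(na$n_neighborhoods)) {
    members <- na$labels == nb
    share <- sum(truth_mask & members) / sum(truth_mask)
    if (share < min_share) next
    if (is.null(truth_labels)) {
      if (sum(truth_mask & members) > sum(members) / 2) return(TRUE)
    } else {
      counts <- table(ifelse(truth_mask[members], "Noise",
                             truth_labels[members]))
      if (names(counts)[which.max(counts)] == "Noise") return(TRUE)
    }
  }
  FALSE
}
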