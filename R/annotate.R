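# Turning cluster assignments into cell-type annotations, and the
# over-clustered reference standard: cluster far beyond the expected number
# of types, then merge highly correlated cluster profiles, so that types
# usually confounded by noise separate before annotation.

#' Per-cell annotation container
#'
#' @param labels character vector, one level-1 cell-type label per cell.
#' @param provenance list describing how the labels were produced, e.g.
#'   `list(kind = "clustered", treatment = "z", algorithm = "leiden")`,
#'   `list(kind = "gated")`, `list(kind = "truth")` or
#'   `list(kind = "overclustered_standard")`.
#' @param mapping optional cluster-id -> type map (when cluster-derived).
#' @return an `annotation_set`.
#' @export
annotation_set <- function(labels, provenance = list(kind = "unknown"),
                           mapping = NULL) {
  structure(list(labels = as.character(labels), provenance = provenance,
                 mapping = mapping),
            class = "annotation_set")
}

#' Mean treated profile of each cluster
#'
#' @param m numeric matrix (cells x markers).
#' @param labels integer cluster labels.
#' @return matrix clusters x markers (rownames = cluster id).
#' @export
cluster_profiles <- function(m, labels) {
  m <- unclass(m)
  ids <- sort(unique(labels))
  out <- matrix(0, length(ids), ncol(m),
                dimnames = list(as.character(ids), colnames(m)))
  for (i in seq_along(ids)) {
    out[i, ] <- colMeans(m[labels == ids[i], , drop = FALSE])
  }
  out
}

#' Annotate clusters by majority vote against a reference
#'
#' Each cluster is mapped to the most frequent reference label among its
#' members (many clusters may map to one type); ties break
#' lexicographically. Stands in for expert annotation when a reference
#' labelling exists; note this surrogate is optimistic for the reference it
#' votes against.
#'
#' @param ca a `cluster_assignment`.
#' @param reference an `annotation_set` on the same cells.
#' @param provenance provenance for the result.
#' @return an `annotation_set`.
#' @export
annotate_by_majority <- function(ca, reference,
                                 provenance = list(kind = "clustered")) {
  stop_if_not(length(ca$labels) == length(reference$labels),
              "cluster assignment and reference must cover the same cells")
  map <- character(ca$n_clusters)
  for (cl in seq_len(ca$n_clusters)) {
    tab <- table(reference$labels[ca$labels == cl])
    top <- names(tab)[tab == max(tab)]
    map[cl] <- min(top)
  }
  annotation_set(map[ca$labels], provenance,
                 mapping = stats::setNames(map, seq_len(ca$n_clusters)))
}

#' Annotate clusters by expected-profile correlation
#'
#' Each cluster is assigned the type whose expected marker profile has the
#' highest Pearson correlation with the cluster's mean treated profile;
#' clusters whose best correlation falls below `floor` (or whose profile has
#' zero variance) become "Unassigned".
#'
#' @param ca a `cluster_assignment`.
#' @param m the treated intensity matrix the clustering ran on.
#' @param profiles types x markers matrix of expected profiles (same marker
#'   order), e.g. [expected_profiles()].
#' @param floor minimum correlation to accept a type.
#' @param provenance provenance for the result.
#' @return an `annotation_set`.
#' @export
annotate_by_profile <- function(ca, m, profiles, floor = 0.2,
                                provenance = list(kind = "clustered")) {
  stop_if_not(nrow(profiles) >= 1, "need at least one expected profile")
  m <- unclass(m)
  stop_if_not(identical(colnames(profiles), colnames(m)),
              "profiles and matrix must share marker order")
  cp <- cluster_profiles(m, ca$labels)
  map <- character(ca$n_clusters)
  for (cl in seq_len(ca$n_clusters)) {
    v <- cp[as.character(cl), ]
    if (stats::sd(v) == 0) {
      warning("cluster ", cl, " has a zero-variance profile; 'Unassigned'")
      map[cl] <- "Unassigned"
      next
    }
    r <- apply(profiles, 1, function(p) {
      if (stats::sd(p) == 0) return(-Inf)
      stats::cor(v, p)
    })
    if (max(r) < floor) {
      map[cl] <- "Unassigned"
    } else {
      top <- names(r)[r == max(r)]
      map[cl] <- min(top)
    }
  }
  annotation_set(map[ca$labels], provenance,
                 mapping = stats::setNames(map, seq_len(ca$n_clusters)))
}

# Correlation between cluster mean profiles, computed after standardizing
# each marker across clusters so high-exposure channels do not dominate the
# Pearson statistic.
profile_correlation <- function(cp) {
  sd <- col_pop_sd(cp)
  sd[sd == 0] <- 1
  zp <- sweep(sweep(cp, 2, colMeans(cp), "-"), 2, sd, "/")
  cc <- suppressWarnings(stats::cor(t(zp)))
  cc[is.na(cc)] <- 1  # zero-variance profiles merge first
  cc
}

# Merge the most-correlated pair of clusters until `target` remain.
merge_to_target <- function(labels, m, target) {
  labels <- as.integer(factor(labels))
  while (max(labels) > target) {
    cp <- cluster_profiles(m, labels)
    cc <- profile_correlation(cp)
    diag(cc) <- -Inf
    idx <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    best <- sort(idx)
    labels[labels == best[2]] <- best[1]
    labels <- as.integer(factor(labels))
  }
  labels
}

#' Build an over-clustered reference standard
#'
#' Clusters the raw intensities far beyond the expected type count with
#' X-shift (angular distance), searching K downward until at least `n_over`
#' clusters appear; trims to exactly `n_over` by iteratively merging the
#' most profile-correlated pair; then agglomeratively merges any clusters
#' whose mean profiles correlate at `merge_corr` or above; finally maps the
#' merged clusters to types by majority vote against `reference` (a
#' surrogate for expert image-overlay annotation), or by expected-profile
#' correlation when only `profiles` is given. A `manual_map` overrides
#' automatic names per cluster id.
#'
#' @param table a `cell_table`.
#' @param reference optional `annotation_set` for majority mapping.
#' @param profiles optional expected-profile matrix for correlation mapping.
#' @param n_over target over-cluster count (default 90).
#' @param merge_corr Pearson threshold for the final merge (<= 1).
#' @param manual_map optional named character vector cluster-id -> type.
#' @param k_search decreasing K values tried for the X-shift run.
#' @return an `annotation_set` with provenance "overclustered_standard" and
#'   attribute `n_merged_clusters` (the post-merge cluster count).
#' @export
build_overclustered_standard <- function(table, reference = NULL,
                                         profiles = NULL,
                                         n_over = 90L, merge_corr = 0.9,
                                         manual_map = NULL,
                                         k_search = c(60L, 45L, 30L, 20L,
                                                      15L, 10L, 7L, 5L, 3L, 2L)) {
  stop_if_not(merge_corr <= 1, "merge_corr must be at most 1")
  stop_if_not(!is.null(reference) || !is.null(profiles),
              "provide a reference annotation or expected profiles")
  m <- intensity_matrix(table)
  stop_if_not(n_over < nrow(m), "n_over must be below the cell count")
  labels <- NULL
  for (K in k_search) {
    ca <- cluster_xshift(m, k = K, metric = "angular", merge_modes = FALSE)
    if (ca$n_clusters >= n_over) { labels <- ca$labels; break }
  }
  if (is.null(labels)) {
    stop("could not reach ", n_over, " clusters; maximum achieved was ",
         ca$n_clusters, call. = FALSE)
  }
  labels <- merge_to_target(labels, m, n_over)
  # agglomerative merge of near-identical profiles
  repeat {
    cp <- cluster_profiles(m, labels)
    if (nrow(cp) <= 2) break
    cc <- profile_correlation(cp)
    diag(cc) <- -Inf
    mx <- max(cc)
    if (mx < merge_corr) break
    idx <- sort(which(cc == mx, arr.ind = TRUE)[1, ])
    labels[labels == idx[2]] <- idx[1]
    labels <- as.integer(factor(labels))
  }
  ca <- cluster_assignment(labels, "xshift_angular")
  ann <- if (!is.null(reference)) {
    annotate_by_majority(ca, reference,
                         provenance = list(kind = "overclustered_standard"))
  } else {
    annotate_by_profile(ca, m, profiles,
                        provenance = list(kind = "overclustered_standard"))
  }
  if (!is.null(manual_map)) {
    for (cl in names(manual_map)) {
      ann$labels[ca$labels == as.integer(cl)] <- manual_map[[cl]]
      ann$mapping[cl] <- manual_map[[cl]]
    }
  }
  attr(ann, "n_merged_clusters") <- ca$n_clusters
  ann
}
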