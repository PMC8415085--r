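# The four unsupervised clustering algorithms compared by the benchmark:
# k-means, Leiden community detection on a kNN graph, and X-shift
# (density-ascent) clustering under Euclidean or angular distance, plus
# elbow-point model selection. All are deterministic given (data, config,
# seed). Cluster ids are compact 1-based integers.

#' Cluster assignment container
#'
#' @param labels integer vector of cluster ids (1..n_clusters, every id
#'   non-empty).
#' @param algorithm algorithm name.
#' @param objective_trace optional named numeric: model-size parameter ->
#'   objective, for elbow diagnostics.
#' @return a `cluster_assignment`.
#' @export
cluster_assignment <- function(labels, algorithm, objective_trace = NULL) {
  labels <- as.integer(factor(labels, levels = sort(unique(labels))))
  structure(list(labels = labels,
                 n_clusters = max(labels),
                 algorithm = algorithm,
                 objective_trace = objective_trace),
            class = "cluster_assignment")
}

#' Angular distance between two vectors
#'
#' `acos` of the cosine similarity, in `[0, pi]`; zero iff the vectors are
#' positive scalar multiples of each other.
#'
#' @param u,v numeric vectors of equal length, each with at least one
#'   nonzero entry.
#' @return nonnegative scalar.
#' @export
angular_distance <- function(u, v) {
  stop_if_not(length(u) == length(v), "vectors must have equal length")
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  stop_if_not(nu > 0 && nv > 0, "angular distance undefined for zero vectors")
  acos(min(1, max(-1, sum(u * v) / (nu * nv))))
}

#' Elbow-point selection on a model-size curve
#'
#' Returns the interior grid value maximizing the discrete second difference
#' `(f(k_prev) - f(k)) - (f(k) - f(k_next))`; ties break to the smallest k.
#' The curve is expected to be monotone non-increasing (warned otherwise).
#'
#' @param curve named numeric vector: model-size parameter -> objective.
#' @return the selected parameter value (numeric).
#' @export
select_elbow <- function(curve) {
  stop_if_not(length(curve) >= 4, "elbow selection needs at least 4 grid points")
  ks <- as.numeric(names(curve))
  stop_if_not(!anyNA(ks) && all(diff(ks) > 0),
              "curve names must be a strictly increasing numeric grid")
  f <- as.numeric(curve)
  if (any(diff(f) > 0)) warning("objective curve is not monotone non-increasing")
  interior <- 2:(length(f) - 1)
  d2 <- (f[interior - 1] - f[interior]) - (f[interior] - f[interior + 1])
  ks[interior[which.max(d2)]]
}

kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(x, 2, x[centers[1], ], "-")^2)
  for (i in seq_len(k - 1)) {
    if (all(d2 == 0)) {
      centers[i + 1] <- sample.int(n, 1)
    } else {
      centers[i + 1] <- sample.int(n, 1, prob = d2)
    }
    nd <- rowSums(sweep(x, 2, x[centers[i + 1], ], "-")^2)
    d2 <- pmin(d2, nd)
  }
  x[centers, , drop = FALSE]
}

kmeans_once <- function(x, k) {
  for (attempt in 1:5) {
    cent <- kmeanspp_centers(x, k)
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = cent, iter.max = 100,
                                     algorithm = "Lloyd")),
      error = function(e) NULL)
    if (!is.null(fit)) return(fit)
  }
  stats::kmeans(x, centers = k, iter.max = 100, nstart = 5)
}

#' k-means clustering
#'
#' Lloyd iterations from kmeans++-style seeding, keeping the best of
#' `restarts` runs by within-cluster sum of squares. If `k_grid` is given
#' instead of `k`, the cluster count is chosen by [select_elbow()] on the
#' WCSS curve.
#'
#' @param m numeric matrix (cells x markers), typically a treated
#'   `intensity_matrix`.
#' @param k number of clusters (>= 2), or NULL to scan `k_grid`.
#' @param k_grid strictly increasing integer grid for the elbow scan.
#' @param seed integer seed.
#' @param restarts independent seeded restarts (best WCSS wins).
#' @return a `cluster_assignment`.
#' @export
cluster_kmeans <- function(m, k = NULL, k_grid = NULL, seed = 0L,
                           restarts = 10L) {
  x <- unclass(m)
  stop_if_not(!is.null(k) || !is.null(k_grid), "provide k or k_grid")
  n_distinct <- nrow(unique(x))
  run_k <- function(kk) {
    stop_if_not(kk >= 2, "k must be at least 2")
    stop_if_not(kk <= n_distinct, "k exceeds the number of distinct rows")
    best <- NULL
    if (kk == 2 && nrow(x) <= 32) {
      # exhaustive seeding over point pairs: on inputs this small, Lloyd
      # from every pair reliably reaches the global WCSS optimum
      n <- nrow(x)
      for (i in 1:(n - 1)) {
        for (j in (i + 1):n) {
          if (all(x[i, ] == x[j, ])) next
          fit <- tryCatch(
            suppressWarnings(stats::kmeans(x, centers = x[c(i, j), ],
                                           iter.max = 100,
                                           algorithm = "Lloyd")),
            error = function(e) NULL)
          if (!is.null(fit) &&
              (is.null(best) || fit$tot.withinss < best$tot.withinss)) {
            best <- fit
          }
        }
      }
      return(best)
    }
    for (r in seq_len(restarts)) {
      fit <- kmeans_once(x, kk)
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    best
  }
  with_local_seed(seed, {
    trace <- NULL
    if (is.null(k)) {
      stop_if_not(all(diff(k_grid) > 0), "k_grid must be strictly increasing")
      fits <- lapply(k_grid, run_k)
      trace <- stats::setNames(vapply(fits, `[[`, 0, "tot.withinss"),
                               k_grid)
      k <- select_elbow(trace)
      best <- fits[[match(k, k_grid)]]
    } else {
      best <- run_k(k)
    }
    cluster_assignment(best$cluster, "kmeans", trace)
  })
}

# Symmetric kNN graph as an igraph object.
knn_graph <- function(x, k) {
  nn <- knn_brute(x, k, "euclidean")
  n <- nrow(x)
  from <- rep(seq_len(n), k)
  to <- as.vector(nn$index)
  igraph::simplify(igraph::graph_from_edgelist(cbind(from, to),
                                               directed = FALSE))
}

#' Leiden graph clustering
#'
#' Builds a symmetric k-nearest-neighbour graph on the treated intensity
#' matrix (Euclidean) and applies Leiden community detection under the
#' modularity objective.
#'
#' @param m numeric matrix (cells x markers).
#' @param resolution Leiden resolution parameter.
#' @param knn_graph_neighbors neighbours per cell for the graph (default 10,
#'   the common single-cell choice).
#' @param seed integer seed.
#' @return a `cluster_assignment`.
#' @export
cluster_leiden <- function(m, resolution = 1.0, knn_graph_neighbors = 10L,
                           seed = 0L) {
  x <- unclass(m)
  stop_if_not(nrow(x) >= knn_graph_neighbors + 1,
              "need at least knn_graph_neighbors + 1 cells")
  if (nrow(unique(x)) == 1) {
    warning("constant matrix; returning a single cluster")
    return(cluster_assignment(rep(1L, nrow(x)), "leiden"))
  }
  g <- knn_graph(x, knn_graph_neighbors)
  with_local_seed(seed, {
    comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                   resolution = resolution,
                                   n_iterations = 5)
    cluster_assignment(igraph::membership(comm), "leiden")
  })
}

# kNN density of arbitrary query points against the data.
query_density <- function(x, q, k, metric) {
  if (metric == "angular") {
    nrm <- sqrt(rowSums(x^2)); nrm[nrm == 0] <- .Machine$double.eps
    xu <- x / nrm
    qn <- sqrt(rowSums(q^2)); qn[qn == 0] <- .Machine$double.eps
    qu <- q / qn
    cs <- tcrossprod(qu, xu)
    cs[cs > 1] <- 1; cs[cs < -1] <- -1
    d <- acos(cs)
  } else {
    d <- sqrt(pmax(outer(rowSums(q^2), rowSums(x^2), "+") -
                     2 * tcrossprod(q, x), 0))
  }
  apply(d, 1, function(di) {
    md <- mean(sort(di)[seq_len(k)])
    if (md > 0) 1 / md else Inf
  })
}

# Merge density-ascent clusters whose modes are connected without a density
# dip: for every pair of clusters joined by a kNN edge, the density is
# profiled along the segment between their modes; if it never falls more
# than a small fraction below the lower of the two mode densities, the two
# clusters belong to one basin and are merged. The tolerance absorbs
# finite-sample noise in the kNN density estimate; a genuine valley between
# separated populations drops the density several-fold. Repeats until
# stable.
merge_modes_by_dip <- function(x, labels, dens, nn_index, k, metric,
                               n_steps = 9L, dip_tolerance = 0.9) {
  n <- nrow(nn_index)
  t <- seq(0, 1, length.out = n_steps + 2L)[-c(1L, n_steps + 2L)]
  repeat {
    nc <- max(labels)
    modes <- vapply(seq_len(nc), function(cl) {
      members <- which(labels == cl)
      members[which.max(dens[members])]
    }, 0L)
    li <- labels[rep(seq_len(n), ncol(nn_index))]
    lj <- labels[as.vector(nn_index)]
    keep <- li != lj
    if (!any(keep)) break
    pa <- pmin(li[keep], lj[keep])
    pb <- pmax(li[keep], lj[keep])
    cross <- unique(cbind(pa, pb))
    # union-find over this round's mergeable pairs
    parent <- seq_len(nc)
    find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
    merged <- FALSE
    for (r in seq_len(nrow(cross))) {
      a <- find(cross[r, 1]); b <- find(cross[r, 2])
      if (a == b) next
      ma <- modes[a]; mb <- modes[b]
      path <- outer(1 - t, x[ma, ]) + outer(t, x[mb, ])
      pd <- query_density(x, path, k, metric)
      if (min(pd) >= dip_tolerance * min(dens[ma], dens[mb])) {
        parent[b] <- a
        merged <- TRUE
      }
    }
    if (!merged) break
    labels <- as.integer(factor(vapply(labels, find, 0L)))
  }
  labels
}

# Density-ascent core: returns integer cluster labels given a kNN index and
# distances. Density = inverse mean kNN distance; each point links to its
# highest-density neighbour when that neighbour is strictly denser (or
# equally dense with a lower index, which makes one mode out of exact ties).
xshift_assign <- function(nn_index, nn_dist) {
  n <- nrow(nn_index)
  md <- rowMeans(nn_dist)
  dens <- ifelse(md > 0, 1 / md, Inf)
  parent <- integer(n)
  for (i in seq_len(n)) {
    nb <- nn_index[i, ]
    dnb <- dens[nb]
    best <- which(dnb == max(dnb))
    j <- nb[best[which.min(nb[best])]]
    if (dens[j] > dens[i] || (dens[j] == dens[i] && j < i)) {
      parent[i] <- j
    } else {
      parent[i] <- i  # mode
    }
  }
  root <- seq_len(n)
  for (i in seq_len(n)) {
    r <- i
    while (parent[r] != r) r <- parent[r]
    # path compression
    j <- i
    while (parent[j] != j) { nxt <- parent[j]; parent[j] <- r; j <- nxt }
    root[i] <- r
  }
  as.integer(factor(root))
}

#' X-shift density-based clustering
#'
#' Re-implementation of kNN-density-ascent clustering: each point's density
#' is the inverse of its mean distance to its K nearest neighbours under the
#' chosen metric; points link to the densest of their K neighbours when it
#' is strictly denser (ties resolve to the lowest cell index, so exact
#' duplicates form a single mode); clusters are the trees rooted at local
#' density modes. If `k_grid` is given, K is chosen by [select_elbow()] on
#' the K -> cluster-count curve.
#'
#' @param m numeric matrix (cells x markers).
#' @param k number of nearest neighbours K (1 < K < n), or NULL to scan.
#' @param k_grid strictly increasing grid of K values for the elbow scan.
#' @param metric "euclidean" or "angular".
#' @return a `cluster_assignment` (algorithm "xshift_euclidean" or
#'   "xshift_angular").
#' @export
cluster_xshift <- function(m, k = NULL, k_grid = NULL,
                           metric = c("euclidean", "angular"),
                           merge_modes = TRUE) {
  metric <- match.arg(metric)
  x <- unclass(m)
  stop_if_not(!is.null(k) || !is.null(k_grid), "provide k or k_grid")
  algo <- paste0("xshift_", metric)
  run_K <- function(nn, K) {
    idx <- nn$index[, seq_len(K), drop = FALSE]
    dst <- nn$dist[, seq_len(K), drop = FALSE]
    labels <- xshift_assign(idx, dst)
    if (merge_modes && max(labels) > 1) {
      md <- rowMeans(dst)
      dens <- ifelse(md > 0, 1 / md, Inf)
      labels <- merge_modes_by_dip(x, labels, dens, idx, K, metric)
    }
    labels
  }
  if (is.null(k)) {
    stop_if_not(all(diff(k_grid) > 0), "k_grid must be strictly increasing")
    kmax <- max(k_grid)
    stop_if_not(kmax < nrow(x), "max of k_grid must be below the cell count")
    nn <- knn_brute(x, kmax, metric)
    counts <- vapply(k_grid, function(K) max(run_K(nn, K)), 0L)
    trace <- stats::setNames(as.numeric(counts), k_grid)
    k <- select_elbow(trace)
    return(cluster_assignment(run_K(nn, k), algo, trace))
  }
  stop_if_not(k > 1 && k < nrow(x), "K must satisfy 1 < K < n_cells")
  nn <- knn_brute(x, k, metric)
  cluster_assignment(run_K(nn, k), algo)
}

#' The four clustering algorithms in benchmark order
#' @return character vector.
#' @export
all_algorithms <- function() {
  c("kmeans", "leiden", "xshift_euclidean", "xshift_angular")
}

#' Run a named clustering algorithm
#'
#' Dispatch helper used by the factorial benchmark.
#'
#' @param m numeric matrix (cells x markers).
#' @param algorithm one of [all_algorithms()].
#' @param seed integer seed.
#' @param kmeans_k cluster count for k-means.
#' @param xshift_k neighbour count K for X-shift.
#' @param leiden_resolution,knn_graph_neighbors Leiden parameters.
#' @return a `cluster_assignment`.
#' @export
run_clustering <- function(m, algorithm, seed = 0L,
                           kmeans_k = 30L, xshift_k = 10L,
                           leiden_resolution = 1.0,
                           knn_graph_neighbors = 10L) {
  switch(algorithm,
         kmeans = cluster_kmeans(m, k = kmeans_k, seed = seed),
         leiden = cluster_leiden(m, resolution = leiden_resolution,
                                 knn_graph_neighbors = knn_graph_neighbors,
                                 seed = seed),
         xshift_euclidean = cluster_xshift(m, k = xshift_k, metric = "euclidean"),
         xshift_angular = cluster_xshift(m, k = xshift_k, metric = "angular"),
         stop("unknown algorithm '", algorithm, "'; valid: ",
              paste(all_algorithms(), collapse = ", "), call. = FALSE))
}
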