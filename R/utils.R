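# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Saves and restores `.Random.seed` so seeded package functions do not
#' perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Population (ddof 0) standard deviation of a vector.
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

# Column-wise population sd of a matrix.
col_pop_sd <- function(m) {
  mu <- colMeans(m)
  sqrt(colMeans(m^2) - mu^2)
}

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

#' k-nearest-neighbour search by brute force
#'
#' Chunked exact kNN under Euclidean or angular distance. Sized for the
#' desk-scale datasets this package works at (thousands of cells), where an
#' exact search is both fast and free of approximation artifacts.
#'
#' @param x numeric matrix (rows = points).
#' @param k number of neighbours (excluding the point itself).
#' @param metric "euclidean" or "angular".
#' @param chunk rows per block when forming the cross-distance matrix.
#' @return list with integer matrix `index` (n x k, neighbour row indices,
#'   nearest first) and numeric matrix `dist` of matching distances.
#' @keywords internal
knn_brute <- function(x, k, metric = c("euclidean", "angular"), chunk = 512L) {
  metric <- match.arg(metric)
  x <- as.matrix(x)
  n <- nrow(x)
  stop_if_not(k >= 1 && k < n, "k must satisfy 1 <= k < nrow(x)")
  if (metric == "angular") {
    nrm <- sqrt(rowSums(x^2))
    nrm[nrm == 0] <- .Machine$double.eps
    xu <- x / nrm
  } else {
    sq <- rowSums(x^2)
  }
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  starts <- seq(1L, n, by = chunk)
  for (s in starts) {
    e <- min(s + chunk - 1L, n)
    rows <- s:e
    if (metric == "euclidean") {
      d2 <- outer(sq[rows], sq, "+") - 2 * tcrossprod(x[rows, , drop = FALSE], x)
      d <- sqrt(pmax(d2, 0))
    } else {
      cs <- tcrossprod(xu[rows, , drop = FALSE], xu)
      cs[cs > 1] <- 1
      cs[cs < -1] <- -1
      d <- acos(cs)
    }
    for (i in seq_along(rows)) {
      di <- d[i, ]
      di[rows[i]] <- Inf
      ord <- order(di, seq_len(n))[seq_len(k)]
      idx[rows[i], ] <- ord
      dst[rows[i], ] <- di[ord]
    }
  }
  list(index = idx, dist = dst)
}
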