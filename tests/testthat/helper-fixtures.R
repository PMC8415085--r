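# Shared fixture builders. Everything is generated in code at test time.

# A minimal hand-sized cell table with two markers.
tiny_table <- function(x = c(0, 10, 20), y = c(0, 0, 0),
                       region = 1, a = c(1, 2, 3), b = c(4, 5, 6)) {
  cell_table(seq_along(x), region, x, y,
             data.frame(A = a, B = b, check.names = FALSE))
}

# Well-separated Gaussian blobs for clustering tests.
make_blobs <- function(centers, n_per = 50, sd = 0.1, seed = 0) {
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  withr_seed({
    x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
      matrix(stats::rnorm(n_per * ncol(centers), 0, sd),
             n_per, ncol(centers)) + rep(centers[i, ], each = n_per)
    }))
    list(x = x, truth = rep(seq_len(nrow(centers)), each = n_per))
  })
}

# Exhaustive-enumeration optimum WCSS over all 2-partitions (oracle for
# k-means on tiny inputs).
brute_force_wcss_k2 <- function(x) {
  n <- nrow(x)
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    grp <- as.integer(intToBits(code))[1:n]
    ss <- 0
    for (g in 0:1) {
      rows <- x[grp == g, , drop = FALSE]
      if (nrow(rows) == 0) { ss <- Inf; break }
      ctr <- colMeans(rows)
      ss <- ss + sum(sweep(rows, 2, ctr, "-")^2)
    }
    if (ss < best) best <- ss
  }
  best
}

# Independent per-type precision/recall/F by direct counting (oracle for
# the evaluation module).
brute_force_prf <- function(ref, pred) {
  types <- sort(union(unique(ref), unique(pred)))
  out <- data.frame(type = types, precision = 0, recall = 0, f_score = 0,
                    stringsAsFactors = FALSE)
  for (i in seq_along(types)) {
    t <- types[i]
    tp <- sum(ref == t & pred == t)
    fp <- sum(ref != t & pred == t)
    fn <- sum(ref == t & pred != t)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    out$precision[i] <- p
    out$recall[i] <- r
    out$f_score[i] <- if (p + r > 0) 2 * p * r / (p + r) else 0
  }
  out
}

# Independent Cohen's kappa by direct counting.
brute_force_kappa <- function(ref, pred) {
  n <- length(ref)
  po <- mean(ref == pred)
  types <- union(unique(ref), unique(pred))
  pe <- sum(vapply(types, function(t) {
    (sum(ref == t) / n) * (sum(pred == t) / n)
  }, 0))
  if (pe >= 1) return(if (po >= 1) 1 else 0)
  (po - pe) / (1 - pe)
}
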