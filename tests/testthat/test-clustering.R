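# k-means, Leiden, X-shift and elbow selection.

test_that("angular distance has the right geometry", {
  expect_equal(angular_distance(c(1, 2), c(2, 4)), 0, tolerance = 1e-7)
  expect_equal(angular_distance(c(1, 0), c(0, 1)), pi / 2)
  expect_equal(angular_distance(c(1, 1), c(-1, -1)), pi)
  expect_error(angular_distance(c(0, 0), c(1, 0)), "zero")
})

test_that("elbow selection maximizes the second difference, ties to smallest k", {
  expect_equal(select_elbow(c("1" = 100, "2" = 50, "3" = 10, "4" = 9, "5" = 8)), 3)
  expect_equal(select_elbow(c("1" = 100, "2" = 20, "3" = 19, "4" = 18)), 2)
  # perfectly linear curve: all second differences 0, smallest interior k wins
  expect_equal(select_elbow(c("2" = 40, "3" = 30, "4" = 20, "5" = 10)), 3)
  expect_error(select_elbow(c("1" = 3, "2" = 2, "3" = 1)), "at least 4")
  expect_warning(select_elbow(c("1" = 1, "2" = 5, "3" = 2, "4" = 1)),
                 "monotone")
})

test_that("k-means separates well-separated pairs and is deterministic", {
  x <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  ca <- cluster_kmeans(x, k = 2, seed = 1)
  expect_equal(ca$labels[1], ca$labels[2])
  expect_equal(ca$labels[3], ca$labels[4])
  expect_false(ca$labels[1] == ca$labels[3])
  ca2 <- cluster_kmeans(x, k = 2, seed = 1)
  expect_identical(ca$labels, ca2$labels)
  expect_error(cluster_kmeans(rbind(c(1, 1), c(1, 1)), k = 2, seed = 1),
               "distinct")
})

test_that("k-means attains the exhaustive-enumeration WCSS optimum on tiny data", {
  set.seed(11)
  for (trial in 1:20) {
    n <- sample(4:8, 1)
    x <- matrix(rnorm(n * 2), n, 2)
    ca <- cluster_kmeans(x, k = 2, seed = trial)
    wcss <- sum(vapply(1:2, function(g) {
      rows <- x[ca$labels == g, , drop = FALSE]
      sum(sweep(rows, 2, colMeans(rows), "-")^2)
    }, 0))
    expect_equal(wcss, brute_force_wcss_k2(x), tolerance = 1e-8)
  }
})

test_that("k-means elbow scan picks k from the WCSS curve", {
  blobs <- make_blobs(rbind(c(0, 0), c(10, 0), c(0, 10)), n_per = 30, seed = 2)
  ca <- cluster_kmeans(blobs$x, k_grid = 2:6, seed = 3)
  expect_equal(ca$n_clusters, 3)
  expect_named(ca$objective_trace, as.character(2:6))
})

test_that("Leiden finds disconnected groups and separated blobs", {
  x <- rbind(matrix(0, 20, 2), matrix(100, 20, 2))
  ca <- cluster_leiden(x, knn_graph_neighbors = 5, seed = 1)
  expect_equal(ca$n_clusters, 2)
  expect_equal(length(unique(ca$labels[1:20])), 1)

  blobs <- make_blobs(rbind(c(0, 0), c(15, 0), c(0, 15)), n_per = 50, seed = 0)
  ca3 <- cluster_leiden(blobs$x, seed = 5)
  expect_gte(ca3$n_clusters, 3)
  # no community ever mixes two blobs (communities refine the truth groups)
  expect_true(all(apply(table(blobs$truth, ca3$labels) > 0, 2, sum) == 1))
  expect_identical(ca3$labels, cluster_leiden(blobs$x, seed = 5)$labels)
})

test_that("X-shift density ascent finds modes and handles ties", {
  one <- make_blobs(rbind(c(0, 0)), n_per = 100, seed = 6)
  expect_equal(cluster_xshift(one$x, k = 15)$n_clusters, 1)
  three <- make_blobs(rbind(c(0, 0), c(12, 0), c(0, 12)), n_per = 50, seed = 7)
  ca <- cluster_xshift(three$x, k = 15)
  expect_equal(ca$n_clusters, 3)
  expect_true(all(apply(table(three$truth, ca$labels) > 0, 1, sum) == 1))
  # identical points: equal densities, index tie-break yields one mode
  same <- matrix(1, 10, 3)
  expect_equal(cluster_xshift(same, k = 3)$n_clusters, 1)
})

test_that("angular X-shift is invariant to per-cell positive rescaling, Euclidean is not", {
  set.seed(8)
  base <- rbind(matrix(rnorm(100, 0, 0.05), 50, 2) + rep(c(1, 0.05), each = 50),
                matrix(rnorm(100, 0, 0.05), 50, 2) + rep(c(0.05, 1), each = 50))
  base <- abs(base)
  scales <- runif(100, 0.5, 20)
  scaled <- base * scales
  a1 <- cluster_xshift(base, k = 10, metric = "angular")$labels
  a2 <- cluster_xshift(scaled, k = 10, metric = "angular")$labels
  expect_identical(a1, a2)
  e1 <- cluster_xshift(base, k = 10, metric = "euclidean")$labels
  e2 <- cluster_xshift(scaled, k = 10, metric = "euclidean")$labels
  expect_false(identical(e1, e2))
})

test_that("X-shift cluster count shrinks as K grows", {
  blobs <- make_blobs(rbind(c(0, 0), c(6, 0), c(0, 6), c(6, 6)),
                      n_per = 40, sd = 0.5, seed = 9)
  n5 <- cluster_xshift(blobs$x, k = 5)$n_clusters
  n40 <- cluster_xshift(blobs$x, k = 40)$n_clusters
  expect_lt(n40, n5)
  # elbow scan over K returns a K from the grid and a trace
  ca <- cluster_xshift(blobs$x, k_grid = c(5, 10, 20, 40), metric = "euclidean")
  expect_named(ca$objective_trace, c("5", "10", "20", "40"))
})

test_that("downstream metrics are invariant to cluster-id permutation", {
  blobs <- make_blobs(rbind(c(0, 0), c(10, 0)), n_per = 30, seed = 10)
  ca <- cluster_kmeans(blobs$x, k = 2, seed = 1)
  ref <- annotation_set(letters[blobs$truth])
  ann1 <- annotate_by_majority(ca, ref)
  flipped <- cluster_assignment(3 - ca$labels, "kmeans")
  ann2 <- annotate_by_majority(flipped, ref)
  expect_identical(ann1$labels, ann2$labels)
})
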