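# Two Manhattan-separated blobs used in several checks: intra-blob
# distances < 2, inter-blob > 10.
two_blobs <- local({
  b1 <- rbind(c(0, 0), c(0.5, 0), c(0, 0.5), c(0.5, 0.5), c(0.25, 0.25),
              c(0.1, 0.4))
  b2 <- b1 + 20
  list(X = rbind(b1, b2), labels = rep(c("a", "b"), each = 6))
})

test_that("PCA reduction preserves full-rank distances and orders variance", {
  set.seed(5)
  basis <- matrix(rnorm(10), 5, 2)
  X <- matrix(rnorm(40), 20, 2) %*% t(basis)  # rank-2 data in 5 dims
  Y <- reduce_pca(X, 2)
  expect_equal(as.matrix(dist(Y)), as.matrix(dist(X)), tolerance = 1e-8,
               ignore_attr = TRUE)
  v <- apply(reduce_pca(matrix(rnorm(200), 50, 4), 4), 2, var)
  expect_true(all(diff(v) <= 1e-12))
  expect_error(reduce_pca(X, 6), "rank")
})

test_that("classical MDS round-trips Euclidean configurations", {
  pts <- rbind(c(0, 0), c(3, 0), c(0, 4), c(3, 4))
  D <- as.matrix(dist(pts))
  Y <- reduce_mds(D, 2)
  expect_equal(as.matrix(dist(Y)), D, tolerance = 1e-6, ignore_attr = TRUE)
  # collinear points recovered in one dimension
  D1 <- as.matrix(dist(c(0, 1, 5)))
  Y1 <- reduce_mds(D1, 1)
  expect_equal(as.matrix(dist(Y1)), D1, tolerance = 1e-6, ignore_attr = TRUE)
  # degenerate all-zero distances: all points coincide (cmdscale warns that
  # no eigenvalue is positive, which is exactly the degenerate case)
  expect_true(all(abs(suppressWarnings(reduce_mds(matrix(0, 4, 4), 2))) < 1e-8))
  expect_error(reduce_mds(matrix(c(0, 1, 2, 0), 2, 2), 1), "symmetric")
  D2 <- as.matrix(dist(pts)); diag(D2) <- 1
  expect_error(reduce_mds(D2, 2), "diagonal")
})

test_that("dbscan recovers separated blobs, degenerate radii behave", {
  res <- dbscan_cluster(two_blobs$X,
                        cluster_config(epsilon = 2, min_points = 3))
  expect_equal(res$n_clusters, 2L)
  expect_true(all(res$assignments > 0L))
  expect_equal(length(unique(res$assignments[1:6])), 1L)
  expect_equal(length(unique(res$assignments[7:12])), 1L)

  tiny <- dbscan_cluster(two_blobs$X,
                         cluster_config(epsilon = 1e-6, min_points = 2))
  expect_equal(tiny$n_clusters, 0L)
  expect_true(all(tiny$assignments == 0L))

  huge <- dbscan_cluster(two_blobs$X,
                         cluster_config(epsilon = 100, min_points = 3))
  expect_equal(huge$n_clusters, 1L)
})

test_that("dbscan matches brute-force density-reachability", {
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(8:30, 1)
    X <- matrix(rnorm(2 * n, sd = sample(c(0.5, 2), 1)), n, 2)
    D <- as.matrix(dist(X, method = "manhattan"))
    eps <- sample(c(0.3, 0.8, 1.5, 3), 1)
    m <- sample(2:5, 1)
    mine <- dbscan_cluster(D, cluster_config(eps, m))$assignments
    expect_equal(mine, brute_dbscan(D, eps, m))
  }
})

test_that("c-Precision reproduces the printed-formula examples", {
  mk <- function(assign) structure(list(assignments = assign,
                                        n_clusters = max(assign)),
                                   class = "cluster_result")
  # cluster {a1, a2, b1} -> 2/3
  r <- c_precision(mk(c(1L, 1L, 1L)), c("a", "a", "b"))
  expect_equal(unname(r$per_cluster_precision), 2 / 3)
  # clusters identical to label groups -> all 1
  r2 <- c_precision(mk(c(1L, 1L, 2L, 2L)), c("a", "a", "b", "b"))
  expect_equal(unname(r2$per_cluster_precision), c(1, 1))
  expect_equal(r2$mean_precision, 1)
  # everything in one cluster, two equal labels -> 0.5
  r3 <- c_precision(mk(rep(1L, 8)), rep(c("a", "b"), 4))
  expect_equal(r3$mean_precision, 0.5)
  # all noise -> undefined
  r4 <- c_precision(mk(c(0L, 0L)), c("a", "b"))
  expect_true(is.na(r4$mean_precision))
})

test_that("c-CSI reproduces the printed-formula examples", {
  mk <- function(assign) structure(list(assignments = assign,
                                        n_clusters = max(c(0L, assign))),
                                   class = "cluster_result")
  # perfect clustering of N points -> 1
  expect_equal(c_csi(mk(c(1L, 1L, 2L, 2L)), c("a", "a", "b", "b")), 1)
  # clusters {a1,a2,b1}, {b2,b3}; labels a:{a1,a2}, b:{b1,b2,b3} -> 4/6
  expect_equal(c_csi(mk(c(1L, 1L, 1L, 2L, 2L)), c("a", "a", "b", "b", "b")),
               2 / 3)
  # all noise -> 0
  expect_equal(c_csi(mk(rep(0L, 5)), rep("a", 5)), 0)
  # unclustered points penalize: same purity, more noise, lower score
  full <- c_csi(mk(c(1L, 1L, 1L, 1L)), rep("a", 4))
  part <- c_csi(mk(c(1L, 1L, 0L, 0L)), rep("a", 4))
  expect_lt(part, full)
})

test_that("metrics are invariant under label renaming", {
  set.seed(9)
  assign <- sample(0:3, 40, replace = TRUE)
  truth <- sample(c("x", "y", "z"), 40, replace = TRUE)
  res <- structure(list(assignments = assign, n_clusters = 3L),
                   class = "cluster_result")
  renamed <- c(x = "epitope_QYI", y = "epitope_HTT", z = "epitope_YLC")[truth]
  expect_equal(c_csi(res, truth), c_csi(res, renamed))
  expect_equal(c_precision(res, truth)$mean_precision,
               c_precision(res, renamed)$mean_precision)
})

test_that("epsilon sweep finds the perfect-clustering window on blobs", {
  sw <- epsilon_sweep(two_blobs$X, two_blobs$labels, min_points = 3)
  expect_equal(sw$epsilon, sort(sw$epsilon))
  expect_true(any(sw$c_csi == 1))
  expect_equal(sw$noise_fraction[1], 1)  # smallest radius: everything noise
  expect_true(all(sw$c_csi >= 0 & sw$c_csi <= 1))
  # c-CSI bounded by mean precision whenever all points are clustered
  full <- sw[sw$noise_fraction == 0 & !is.na(sw$mean_precision), ]
  expect_true(all(full$c_csi <= full$mean_precision + 1e-12))
})

test_that("well-separated gaussian blobs cluster perfectly at a suitable radius", {
  tb <- simulate_embedding_testbed(n_points_per_label = 30, n_labels = 3,
                                   separation = 50, noise_sd = 1, seed = 4)
  sw <- epsilon_sweep(tb$X, tb$labels, min_points = 5)
  expect_true(any(sw$c_csi == 1))
})
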