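# Density-based clustering of TCR embeddings and the purity metrics used to
# score clusterings against epitope labels.  DBSCAN is implemented here
# (queue-based cluster expansion over a precomputed distance matrix); the
# test suite checks it against an independent brute-force density-
# reachability closure.

#' Clustering configuration
#'
#' @param epsilon neighborhood radius.
#' @param min_points minimum neighborhood size (self-inclusive) for a core
#'   point; default 5.
#' @param metric `"manhattan"` (default, matching the embedding analysis)
#'   or `"euclidean"`.
#' @return list of class `cluster_config`.
#' @export
cluster_config <- function(epsilon, min_points = 5L,
                           metric = c("manhattan", "euclidean")) {
  stopifnot(epsilon > 0, min_points >= 1)
  structure(list(epsilon = epsilon, min_points = as.integer(min_points),
                 metric = match.arg(metric)),
            class = "cluster_config")
}

#' Reduce an embedding matrix by PCA
#'
#' Principal components of the mean-centered matrix, ordered by decreasing
#' variance; 24 dimensions is the default used before clustering.
#'
#' @param X numeric matrix (rows = points).
#' @param n number of components.
#' @return matrix with `n` columns.
#' @export
reduce_pca <- function(X, n = 24L) {
  X <- as.matrix(X)
  if (n > min(dim(X))) stop("n exceeds the rank bound min(rows, cols)")
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  p$x[, seq_len(n), drop = FALSE]
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Double-centered Gram eigendecomposition; for a Euclidean distance matrix
#' of intrinsic dimension <= n the pairwise distances are recovered exactly.
#' Used to project precomputed CDR3 distance matrices before clustering.
#'
#' @param D symmetric non-negative matrix with zero diagonal.
#' @param n target dimension.
#' @return matrix with `n` columns (rows = points).
#' @export
reduce_mds <- function(D, n = 24L) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(D < 0)) stop("distance matrix must be non-negative")
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix must have a zero diagonal")
  out <- stats::cmdscale(D, k = n)
  if (ncol(out) < n)  # degenerate spectra yield fewer positive eigenvalues
    out <- cbind(out, matrix(0, nrow(out), n - ncol(out)))
  out
}

#' Density-based clustering (DBSCAN)
#'
#' Core points have at least `min_points` points (including themselves)
#' within distance `epsilon`; clusters are maximal density-connected sets;
#' points reachable from no core point are noise (cluster id `0`).  Border
#' points join the first cluster that reaches them, with discovery order
#' fixed by input order, so results are deterministic.
#'
#' @param X numeric matrix of points, or a `dist`/square distance matrix
#'   (then `metric` is ignored).
#' @param config a [cluster_config()].
#' @return list of class `cluster_result`: `assignments` (integer vector,
#'   0 = noise, clusters numbered 1.. in discovery order), `n_clusters`,
#'   and `is_core` (logical vector).
#' @export
dbscan_cluster <- function(X, config) {
  stopifnot(inherits(config, "cluster_config"))
  D <- if (inherits(X, "dist")) as.matrix(X)
       else if (is.matrix(X) && nrow(X) == ncol(X) &&
                isSymmetric(unname(X), tol = 1e-8) && all(diag(X) == 0)) X
       else as.matrix(stats::dist(X, method = config$metric))
  n <- nrow(D)
  if (!n) stop("empty input")
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= config$epsilon))
  core <- vapply(nb, length, integer(1)) >= config$min_points
  assign <- integer(n)  # 0 = unvisited/noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (assign[i] != 0L || !core[i]) next
    cl <- cl + 1L
    assign[i] <- cl
    frontier <- i
    while (length(frontier)) {
      cores <- frontier[core[frontier]]
      if (!length(cores)) break
      cand <- unique(unlist(nb[cores], use.names = FALSE))
      cand <- cand[assign[cand] == 0L]
      if (!length(cand)) break
      assign[cand] <- cl
      frontier <- cand
    }
  }
  structure(list(assignments = assign, n_clusters = cl, is_core = core),
            class = "cluster_result")
}

#' Per-cluster precision against epitope labels
#'
#' For each cluster \eqn{C_i}, precision is
#' \eqn{\max_j |C_i \cap L_j| / |C_i|} where \eqn{L_j} are the label
#' groups.  Noise points belong to no cluster.  The mean is size-weighted
#' over clusters (an unweighted mean is also returned).
#'
#' @param result a `cluster_result`.
#' @param truth vector of labels, one per point.
#' @return list of class `cluster_metrics`: `per_cluster_precision`,
#'   `mean_precision` (size-weighted), `mean_precision_unweighted`.
#'   All `NA` when every point is noise.
#' @export
c_precision <- function(result, truth) {
  stopifnot(length(truth) == length(result$assignments))
  a <- result$assignments
  if (!any(a > 0L))
    return(structure(list(per_cluster_precision = numeric(0),
                          mean_precision = NA_real_,
                          mean_precision_unweighted = NA_real_),
                     class = "cluster_metrics"))
  sizes <- table(a[a > 0L])
  best <- vapply(names(sizes), function(ci)
    max(table(truth[a == as.integer(ci)])), numeric(1))
  prec <- best / as.numeric(sizes)
  structure(list(per_cluster_precision = stats::setNames(prec, names(sizes)),
                 mean_precision = sum(best) / sum(sizes),
                 mean_precision_unweighted = mean(prec)),
            class = "cluster_metrics")
}

#' Clustering critical success index
#'
#' \deqn{cCSI = \frac{\sum_i \max_j |C_i \cap L_j|}
#'   {\sum_i |C_i| + \sum_j |L_j| - \sum_i \max_j |C_i \cap L_j|}}
#' Noise points count in the label totals but in no cluster, so leaving
#' points unclustered lowers the score; a perfect clustering of all points
#' scores 1.
#'
#' @inheritParams c_precision
#' @return a number in [0, 1].
#' @export
c_csi <- function(result, truth) {
  stopifnot(length(truth) == length(result$assignments))
  a <- result$assignments
  hits <- 0
  if (any(a > 0L))
    hits <- sum(vapply(unique(a[a > 0L]), function(ci)
      max(table(truth[a == ci])), numeric(1)))
  denom <- sum(a > 0L) + length(truth) - hits
  if (denom == 0) return(1)  # no points at all is vacuously perfect
  hits / denom
}

#' Sweep the DBSCAN radius and score each clustering
#'
#' @param X points or distance matrix (see [dbscan_cluster()]).
#' @param truth labels, one per point.
#' @param eps_values radii to evaluate; default 50 log-spaced values over
#'   0.01--20.
#' @param min_points,metric passed to [cluster_config()].
#' @return data.frame with one row per epsilon: `epsilon`, `n_clusters`,
#'   `noise_fraction`, `mean_precision`, `c_csi`.
#' @export
epsilon_sweep <- function(X, truth,
                          eps_values = exp(seq(log(0.01), log(20),
                                               length.out = 50)),
                          min_points = 5L,
                          metric = c("manhattan", "euclidean")) {
  if (!length(eps_values)) stop("empty epsilon sweep")
  metric <- match.arg(metric)
  eps_values <- sort(eps_values)
  D <- if (inherits(X, "dist")) as.matrix(X)
       else if (is.matrix(X) && nrow(X) == ncol(X) &&
                isSymmetric(unname(X), tol = 1e-8) && all(diag(X) == 0)) X
       else as.matrix(stats::dist(X, method = metric))
  rows <- lapply(eps_values, function(eps) {
    res <- dbscan_cluster(D, cluster_config(eps, min_points, metric))
    pr <- c_precision(res, truth)
    data.frame(epsilon = eps, n_clusters = res$n_clusters,
               noise_fraction = mean(res$assignments == 0L),
               mean_precision = pr$mean_precision,
               c_csi = c_csi(res, truth))
  })
  do.call(rbind, rows)
}
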