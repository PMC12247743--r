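# Labeled TCR-epitope pair handling, the similarity-guided 80/20 split,
# negative-pair generation, and the random-forest binding classifier
# evaluated by auROC.

#' Construct a table of binding pairs
#'
#' @param cdr3,epitope character vectors of equal length.
#' @param label `"positive"`/`"negative"` (default all positive).
#' @param origin `"observed"`, `"shuffled"` or `"swapped"`.
#' @param antigen_group optional grouping of epitopes into antigens.
#' @return data.frame of class `binding_pairs` with a unique `id` column.
#' @export
binding_pairs <- function(cdr3, epitope, label = "positive",
                          origin = "observed", antigen_group = NA_character_) {
  stopifnot(length(cdr3) == length(epitope))
  df <- data.frame(id = paste0("p", seq_along(cdr3)), cdr3 = cdr3,
                   epitope = epitope, label = label, origin = origin,
                   antigen_group = antigen_group, stringsAsFactors = FALSE)
  structure(df, class = c("binding_pairs", "data.frame"))
}

#' Drop epitopes with sparse TCR support
#'
#' Retains only pairs whose epitope has at least `min_tcrs` distinct
#' associated TCRs among the positive pairs (default 1000, the depth filter
#' applied before classification and clustering).
#'
#' @param pairs a `binding_pairs` data.frame.
#' @param min_tcrs minimum distinct positive TCRs per epitope.
#' @return the filtered pairs.
#' @export
filter_epitopes <- function(pairs, min_tcrs = 1000L) {
  stopifnot(min_tcrs >= 1)
  pos <- pairs[pairs$label == "positive", c("cdr3", "epitope")]
  counts <- tapply(pos$cdr3, pos$epitope, function(x) length(unique(x)))
  keep <- names(counts)[counts >= min_tcrs]
  pairs[pairs$epitope %in% keep, , drop = FALSE]
}

#' One-hot encode a peptide sequence
#'
#' Position p (0-based), residue a maps to index `20 p + rank(a)` with
#' alphabetical rank over ACDEFGHIKLMNPQRSTVWY; positions beyond the
#' sequence are zero.
#'
#' @param seq peptide sequence.
#' @param max_len padded length; sequences longer than this are an error.
#' @return numeric vector of length `20 * max_len`.
#' @export
one_hot_encode <- function(seq, max_len) {
  assert_peptide(seq)
  n <- nchar(seq)
  if (n > max_len) stop("sequence longer than max_len (", n, " > ", max_len, ")")
  v <- numeric(20L * max_len)
  ranks <- match(strsplit(seq, "")[[1]], AA_ALPHABET)
  v[20L * (seq_len(n) - 1L) + ranks] <- 1
  v
}

#' Similarity-guided train/test split
#'
#' Per epitope group: seed TCRs are drawn at random and grouped with their
#' nearest neighbors (exact k-NN under L2 distance on one-hot encodings);
#' seed plus neighbors go to the test side until the epitope's quota
#' (`test_fraction` of its distinct TCRs) is met.  Assignment happens at
#' the level of distinct CDR3 strings, so identical strings can never end
#' up on both sides, and no (tcr, epitope) pair is shared between sides.
#'
#' @param pairs a `binding_pairs` data.frame (typically positives).
#' @param test_fraction fraction of each epitope's TCRs held out
#'   (default 0.2).
#' @param seed integer seed.
#' @param group_size neighbors grouped per seed draw (default 10).
#' @return list of class `split_assignment`: `train_ids`, `test_ids`
#'   (pair ids), `test_fraction`, `seed`, and `flagged` (epitopes too small
#'   to split, all sent to train).
#' @export
similarity_split <- function(pairs, test_fraction = 0.2, seed = 1L,
                             group_size = 10L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  rng <- .local_rng(seed)
  train_ids <- test_ids <- character(0)
  flagged <- character(0)
  for (e in unique(pairs$epitope)) {
    sub <- pairs[pairs$epitope == e, , drop = FALSE]
    tcrs <- unique(sub$cdr3)
    if (length(tcrs) < 2L) {
      flagged <- c(flagged, e)
      train_ids <- c(train_ids, sub$id)
      next
    }
    quota <- round(test_fraction * length(tcrs))
    quota <- max(1L, min(quota, length(tcrs) - 1L))
    max_len <- max(nchar(tcrs))
    X <- t(vapply(tcrs, one_hot_encode, numeric(20L * max_len),
                  max_len = max_len))
    remaining <- seq_along(tcrs)
    test_idx <- integer(0)
    while (length(test_idx) < quota && length(remaining)) {
      seed_i <- remaining[rng$int(length(remaining))]
      d2 <- colSums((t(X[remaining, , drop = FALSE]) - X[seed_i, ])^2)
      need <- min(group_size, quota - length(test_idx), length(remaining))
      ord <- remaining[order(d2, remaining)]  # seed first (distance 0)
      take <- ord[seq_len(need)]
      test_idx <- c(test_idx, take)
      remaining <- setdiff(remaining, take)
    }
    test_tcrs <- tcrs[test_idx]
    test_ids <- c(test_ids, sub$id[sub$cdr3 %in% test_tcrs])
    train_ids <- c(train_ids, sub$id[!(sub$cdr3 %in% test_tcrs)])
  }
  structure(list(train_ids = train_ids, test_ids = test_ids,
                 test_fraction = test_fraction, seed = as.integer(seed),
                 flagged = flagged),
            class = "split_assignment")
}

# Small deterministic RNG independent of R's global .Random.seed, so
# splitting/negatives never perturb (or depend on) user RNG state.
.local_rng <- function(seed) {
  state <- as.double(seed %% 2147483647)
  if (state <= 0) state <- state + 2147483646
  nxt <- function() {
    state <<- (state * 48271) %% 2147483647
    state / 2147483647
  }
  list(unif = nxt,
       int = function(n) as.integer(floor(nxt() * n)) + 1L)
}

#' Generate negative TCR-epitope pairs
#'
#' `shuffle`: each negative pairs a TCR with an epitope that is not among
#' its cognate epitopes.  `swap_groups`: the epitope must additionally come
#' from a different antigen group than every cognate epitope of that TCR.
#' No duplicate negatives and no accidental positives are produced; TCRs
#' cognate to every epitope (or every group) are skipped with a warning.
#'
#' @param positives a `binding_pairs` data.frame of positive pairs.
#' @param strategy `"shuffle"` or `"swap_groups"`.
#' @param ratio negatives per positive (default 1).
#' @param seed integer seed.
#' @param groups optional named vector epitope -> antigen group (defaults
#'   to the `antigen_group` column for `swap_groups`).
#' @return a `binding_pairs` data.frame of negatives (label `"negative"`,
#'   origin `"shuffled"` or `"swapped"`).
#' @export
generate_negatives <- function(positives, strategy = c("shuffle", "swap_groups"),
                               ratio = 1.0, seed = 1L, groups = NULL) {
  strategy <- match.arg(strategy)
  epitopes <- unique(positives$epitope)
  if (strategy == "shuffle" && length(epitopes) < 2L)
    stop("shuffle strategy needs at least 2 distinct epitopes")
  if (strategy == "swap_groups") {
    if (is.null(groups))
      groups <- tapply(positives$antigen_group, positives$epitope,
                       function(x) x[1])
    if (length(unique(groups[epitopes])) < 2L)
      stop("swap_groups strategy needs at least 2 antigen groups")
  }
  cognate <- tapply(positives$epitope, positives$cdr3, unique)
  tcrs <- names(cognate)
  target <- round(ratio * nrow(positives))
  rng <- .local_rng(seed + 7L)
  seen <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(positives)))
    assign(paste0(positives$cdr3[i], "\r", positives$epitope[i]), TRUE,
           envir = seen)
  out_t <- out_e <- character(target)
  got <- 0L
  attempts <- 0L
  warned <- FALSE
  while (got < target && attempts < 50L * target) {
    attempts <- attempts + 1L
    tcr <- tcrs[rng$int(length(tcrs))]
    cand <- setdiff(epitopes, cognate[[tcr]])
    if (strategy == "swap_groups")
      cand <- cand[!(groups[cand] %in% groups[cognate[[tcr]]])]
    if (!length(cand)) {
      if (!warned) {
        warning("TCR(s) cognate to all epitopes/groups skipped")
        warned <- TRUE
      }
      next
    }
    epi <- cand[rng$int(length(cand))]
    key <- paste0(tcr, "\r", epi)
    if (exists(key, envir = seen, inherits = FALSE)) next
    assign(key, TRUE, envir = seen)
    got <- got + 1L
    out_t[got] <- tcr
    out_e[got] <- epi
  }
  if (got < target)
    warning("generated ", got, " of ", target, " requested negatives")
  df <- data.frame(id = paste0("n", seq_len(got)), cdr3 = out_t[seq_len(got)],
                   epitope = out_e[seq_len(got)], label = "negative",
                   origin = if (strategy == "shuffle") "shuffled" else "swapped",
                   antigen_group = NA_character_, stringsAsFactors = FALSE)
  structure(df, class = c("binding_pairs", "data.frame"))
}

#' Concatenated pair features
#'
#' @param tcr_vec,epi_vec embedding rows of equal width d.
#' @return numeric vector of length 2d, TCR first.
#' @export
pair_features <- function(tcr_vec, epi_vec) {
  if (length(tcr_vec) != length(epi_vec))
    stop("embedding dimensionality mismatch (",
         length(tcr_vec), " vs ", length(epi_vec), ")")
  c(tcr_vec, epi_vec)
}

#' Train the random-forest binding classifier
#'
#' @param features numeric matrix (rows = pairs).
#' @param labels binary vector (1/"positive" = binding).
#' @param n_trees number of trees (default 500).
#' @param max_depth maximum tree depth; `0` (default) means unlimited.
#' @param seed integer seed; training is single-threaded for determinism.
#' @return object of class `binding_classifier`; use [predict_scores()].
#' @export
train_classifier <- function(features, labels, n_trees = 500L,
                             max_depth = 0L, seed = 1L) {
  y <- .as_binary(labels)
  if (length(unique(y)) < 2L) stop("need at least one example per class")
  df <- as.data.frame(features)
  colnames(df) <- paste0("f", seq_len(ncol(df)))
  df$.y <- factor(y, levels = c(0, 1))
  fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                        num.trees = n_trees, max.depth = max_depth,
                        probability = TRUE, seed = seed, num.threads = 1L,
                        verbose = FALSE)
  structure(list(fit = fit, n_features = ncol(features)),
            class = "binding_classifier")
}

.as_binary <- function(labels) {
  if (is.character(labels) || is.factor(labels))
    as.integer(as.character(labels) == "positive")
  else as.integer(labels != 0)
}

#' Predict binding probabilities
#'
#' @param model a `binding_classifier`.
#' @param features numeric matrix with the training feature width.
#' @return numeric vector of probabilities of the positive class.
#' @export
predict_scores <- function(model, features) {
  stopifnot(inherits(model, "binding_classifier"))
  df <- as.data.frame(features)
  colnames(df) <- paste0("f", seq_len(ncol(df)))
  stats::predict(model$fit, data = df, num.threads = 1L)$predictions[, "1"]
}

#' Area under the ROC curve
#'
#' Computed as the rank statistic: the probability that a random positive
#' outscores a random negative, with ties counted one half (equivalently,
#' the trapezoidal area under the ROC curve).
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels binary labels (1/"positive" = positive class).
#' @return list of class `roc_result`: `auroc`, `curve` (data.frame fpr,
#'   tpr from (0,0) to (1,1)), `n_pos`, `n_neg`.
#' @export
evaluate_auroc <- function(scores, labels) {
  y <- .as_binary(labels)
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auroc <- (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(-scores)
  tp <- cumsum(y[ord] == 1L); fp <- cumsum(y[ord] == 0L)
  keep <- c(diff(scores[ord]) != 0, TRUE)  # one point per threshold
  curve <- data.frame(fpr = c(0, fp[keep] / n_neg),
                      tpr = c(0, tp[keep] / n_pos))
  structure(list(auroc = auroc, curve = curve, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' Cross-validated grid evaluation of WL iterations and dimensions
#'
#' Pairs are split into `k_folds` folds stratified by epitope; for each
#' grid cell the pooled corpus is re-embedded with that (wl, dim) setting
#' and a random forest is trained on the training folds and scored on the
#' validation fold.  Reports mean validation auROC per cell.
#'
#' @param pairs labeled `binding_pairs` (positives and negatives).
#' @param k_folds number of folds (default 5).
#' @param wl_grid,dim_grid parameter grids.
#' @param seed integer seed.
#' @param epochs,n_trees training budgets.
#' @return data.frame: `wl_iterations`, `dimensions`, `mean_auroc`.
#' @export
cross_validate <- function(pairs, k_folds = 5L, wl_grid = c(3L, 5L),
                           dim_grid = c(32L, 64L), seed = 1L,
                           epochs = 10L, n_trees = 200L) {
  stopifnot(k_folds >= 2L)
  if (nrow(pairs) < k_folds) stop("too few pairs for the requested folds")
  rng <- .local_rng(seed + 11L)
  folds <- integer(nrow(pairs))
  for (e in unique(pairs$epitope)) {          # stratified by epitope
    idx <- which(pairs$epitope == e)
    perm <- idx[order(vapply(idx, function(i) rng$unif(), numeric(1)))]
    folds[perm] <- rep_len(seq_len(k_folds), length(perm))
  }
  grid <- expand.grid(wl_iterations = wl_grid, dimensions = dim_grid)
  grid$mean_auroc <- NA_real_
  for (gi in seq_len(nrow(grid))) {
    em <- embed_sequences(unique(c(pairs$cdr3, pairs$epitope)),
                          k = grid$wl_iterations[gi],
                          dimensions = grid$dimensions[gi],
                          epochs = epochs, seed = seed)
    feats <- .pair_feature_matrix(pairs, em)
    aucs <- vapply(seq_len(k_folds), function(f) {
      tr <- folds != f; te <- !tr
      if (length(unique(pairs$label[te])) < 2L) return(NA_real_)
      m <- train_classifier(feats[tr, , drop = FALSE], pairs$label[tr],
                            n_trees = n_trees, seed = seed)
      evaluate_auroc(predict_scores(m, feats[te, , drop = FALSE]),
                     pairs$label[te])$auroc
    }, numeric(1))
    grid$mean_auroc[gi] <- mean(aucs, na.rm = TRUE)
  }
  grid
}

.pair_feature_matrix <- function(pairs, em) {
  v <- em$vectors[match(pairs$cdr3, em$graph_ids), , drop = FALSE]
  w <- em$vectors[match(pairs$epitope, em$graph_ids), , drop = FALSE]
  if (anyNA(v) || anyNA(w)) stop("pair sequence missing from the embedding")
  unname(cbind(v, w))
}

#' Down-sampling experiment
#'
#' After splitting, both sides are down-sampled at each ratio, the corpus
#' re-embedded on the reduced data, and the classifier re-fit; reports test
#' auROC per ratio, probing how data depth drives performance.
#'
#' @param pairs labeled `binding_pairs` (positives and negatives).
#' @param split a [similarity_split()] result for these pairs.
#' @param ratios subsampling ratios in (0, 1].
#' @param seed integer seed.
#' @param k,dimensions,epochs,n_trees pipeline settings.
#' @return data.frame: `ratio`, `n_train`, `n_test`, `auroc`.
#' @export
downsample_experiment <- function(pairs, split, ratios = seq(0.2, 1, by = 0.2),
                                  seed = 1L, k = 5L, dimensions = 64L,
                                  epochs = 10L, n_trees = 200L) {
  stopifnot(all(ratios > 0), all(ratios <= 1))
  rows <- lapply(ratios, function(r) {
    rng <- .local_rng(seed + round(1000 * r))
    pick <- function(ids) {
      n <- max(1L, round(r * length(ids)))
      ids[order(vapply(ids, function(i) rng$unif(), numeric(1)))][seq_len(n)]
    }
    tr <- pairs[pairs$id %in% pick(split$train_ids), , drop = FALSE]
    te <- pairs[pairs$id %in% pick(split$test_ids), , drop = FALSE]
    if (length(unique(tr$label)) < 2L || length(unique(te$label)) < 2L)
      stop("ratio ", r, " leaves an empty class")
    em <- embed_sequences(unique(c(tr$cdr3, tr$epitope, te$cdr3, te$epitope)),
                          k = k, dimensions = dimensions, epochs = epochs,
                          seed = seed)
    m <- train_classifier(.pair_feature_matrix(tr, em), tr$label,
                          n_trees = n_trees, seed = seed)
    auc <- evaluate_auroc(predict_scores(m, .pair_feature_matrix(te, em)),
                          te$label)$auroc
    data.frame(ratio = r, n_train = nrow(tr), n_test = nrow(te), auroc = auc)
  })
  do.call(rbind, rows)
}
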