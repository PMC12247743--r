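test_that("epitope depth filtering respects the boundary exactly", {
  pairs <- binding_pairs(
    cdr3 = c(paste0("CASS", strrep("A", 1:5), "F"), "CASSGF"),
    epitope = c(rep("deep", 5), "shallow"))
  expect_equal(unique(filter_epitopes(pairs, min_tcrs = 5)$epitope), "deep")
  expect_equal(nrow(filter_epitopes(pairs, min_tcrs = 6)), 0L)
  expect_equal(filter_epitopes(pairs, min_tcrs = 1), pairs)
  # duplicated CDR3 strings count once toward the depth
  dup <- binding_pairs(rep("CASSLF", 3), rep("e", 3))
  expect_equal(nrow(filter_epitopes(dup, min_tcrs = 2)), 0L)
})

test_that("one-hot encoding places residues at 20p + rank(a)", {
  v <- one_hot_encode("CAS", max_len = 5)
  expect_length(v, 100L)
  expect_equal(sum(v), 3)
  expect_equal(which(v == 1), c(0 * 20 + 2, 1 * 20 + 1, 2 * 20 + 16))
  expect_equal(one_hot_encode("CAS", 5), one_hot_encode("CAS", 5))
  expect_equal(sum((one_hot_encode("A", 1) - one_hot_encode("C", 1))^2), 2)
  expect_error(one_hot_encode("CASSL", 4), "longer than max_len")
})

test_that("the similarity split leaks neither pairs nor CDR3 strings", {
  sim <- simulate_repertoire(3, 60, seed = 5)
  pairs <- sim$pairs
  for (s in c(1L, 2L, 3L)) {
    sp <- similarity_split(pairs, test_fraction = 0.2, seed = s)
    expect_length(intersect(sp$train_ids, sp$test_ids), 0L)
    tr <- pairs[pairs$id %in% sp$train_ids, ]
    te <- pairs[pairs$id %in% sp$test_ids, ]
    expect_equal(nrow(tr) + nrow(te), nrow(pairs))
    expect_length(intersect(paste(tr$cdr3, tr$epitope),
                            paste(te$cdr3, te$epitope)), 0L)
    for (e in unique(pairs$epitope))
      expect_length(intersect(tr$cdr3[tr$epitope == e],
                              te$cdr3[te$epitope == e]), 0L)
    # quota: test size within one neighbor group of the target fraction
    frac <- nrow(te) / nrow(pairs)
    expect_lt(abs(frac - 0.2), 10 / 60 + 0.02)
  }
})

test_that("duplicated CDR3 strings land on one side of the split", {
  cdr3 <- c(rep("CASSAAAF", 2), paste0("CASS", strrep("G", 1:8), "F"))
  pairs <- binding_pairs(cdr3, rep("e1", 10))
  pairs <- rbind(pairs, binding_pairs(paste0("CASS", strrep("W", 1:5), "F"),
                                      rep("e2", 5)))
  pairs$id <- paste0("p", seq_len(nrow(pairs)))
  sp <- similarity_split(pairs, 0.3, seed = 2)
  dup_ids <- pairs$id[pairs$cdr3 == "CASSAAAF"]
  expect_true(all(dup_ids %in% sp$train_ids) ||
              all(dup_ids %in% sp$test_ids))
  # an epitope with a single TCR cannot be split and is flagged into train
  one <- rbind(pairs, binding_pairs("CASSYYYF", "lonely"))
  one$id <- paste0("q", seq_len(nrow(one)))
  sp1 <- similarity_split(one, 0.2, seed = 1)
  expect_true("lonely" %in% sp1$flagged)
})

test_that("generated negatives avoid cognate pairs and hit the requested count", {
  sim <- simulate_repertoire(4, 30, seed = 8)
  pos <- sim$pairs
  neg <- generate_negatives(pos, "shuffle", ratio = 1.0, seed = 3)
  expect_equal(nrow(neg), nrow(pos))
  expect_true(all(neg$label == "negative"))
  expect_true(all(neg$origin == "shuffled"))
  expect_length(intersect(paste(neg$cdr3, neg$epitope),
                          paste(pos$cdr3, pos$epitope)), 0L)
  expect_equal(anyDuplicated(paste(neg$cdr3, neg$epitope)), 0L)
  half <- generate_negatives(pos, "shuffle", ratio = 0.5, seed = 3)
  expect_equal(nrow(half), round(0.5 * nrow(pos)))

  # swap_groups: negatives cross antigen-group boundaries
  groups <- stats::setNames(rep(c("g1", "g2"), each = 2),
                            unique(pos$epitope))
  sw <- generate_negatives(pos, "swap_groups", ratio = 0.5, seed = 4,
                           groups = groups)
  cognate <- tapply(pos$epitope, pos$cdr3, unique)
  for (r in seq_len(nrow(sw)))
    expect_false(groups[sw$epitope[r]] %in%
                 groups[cognate[[sw$cdr3[r]]]])

  single <- pos[pos$epitope == pos$epitope[1], ]
  expect_error(generate_negatives(single, "shuffle"), "at least 2")
})

test_that("pair features concatenate TCR-first", {
  a <- c(1, 2); b <- c(3, 4)
  expect_equal(pair_features(a, b), c(1, 2, 3, 4))
  expect_false(identical(pair_features(a, b), pair_features(b, a)))
  expect_equal(pair_features(numeric(3), numeric(3)), numeric(6))
  expect_error(pair_features(1:2, 1:3), "mismatch")
})

test_that("auROC follows the rank statistic with half ties", {
  r <- evaluate_auroc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))
  expect_equal(r$auroc, 0.75)
  expect_equal(r$n_pos, 2L)
  expect_equal(r$curve[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(unlist(r$curve[nrow(r$curve), ]), c(fpr = 1, tpr = 1))
  expect_equal(evaluate_auroc(c(5, 4, 2, 1), c(1, 1, 0, 0))$auroc, 1)
  expect_equal(evaluate_auroc(rep(1, 6), c(1, 0, 1, 0, 1, 0))$auroc, 0.5)
  expect_error(evaluate_auroc(1:3, c(1, 1, 1)), "both classes")
})

test_that("auROC equals brute-force pair enumeration on random vectors", {
  set.seed(31)
  for (rep in 1:40) {
    n <- sample(6:50, 1)
    scores <- round(runif(n), sample(c(1, 2), 1))  # induce ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(evaluate_auroc(scores, labels)$auroc,
                 brute_auroc(scores, labels))
  }
})

test_that("the random forest separates separable data and is seed-stable", {
  set.seed(17)
  X <- rbind(matrix(rnorm(200, 0), 50), matrix(rnorm(200, 3), 50))
  y <- rep(c(0, 1), each = 50)
  m <- train_classifier(X, y, n_trees = 100, seed = 5)
  s <- predict_scores(m, X)
  expect_gte(evaluate_auroc(s, y)$auroc, 0.99)
  m2 <- train_classifier(X, y, n_trees = 100, seed = 5)
  expect_identical(predict_scores(m2, X), s)
  # depth sweep stays finite
  for (d in c(1L, 7L, 15L)) {
    md <- train_classifier(X, y, n_trees = 50, max_depth = d, seed = 5)
    expect_true(all(is.finite(predict_scores(md, X))))
  }
  expect_error(train_classifier(X, rep(1, 100)), "per class")
})

test_that("cross-validation folds are pair-disjoint and epitope-stratified", {
  sim <- simulate_repertoire(3, 25, cdr3_length_range = c(10, 12), seed = 6)
  pos <- sim$pairs
  neg <- generate_negatives(pos, "shuffle", 1.0, seed = 2)
  pairs <- rbind(pos, neg)
  tab <- cross_validate(pairs, k_folds = 3, wl_grid = 2L, dim_grid = 16L,
                        seed = 9, epochs = 4, n_trees = 50)
  expect_equal(nrow(tab), 1L)
  expect_true(is.finite(tab$mean_auroc))
  expect_true(tab$mean_auroc >= 0 && tab$mean_auroc <= 1)
})

test_that("down-sampling at ratio 1 reproduces the full pipeline result", {
  sim <- simulate_repertoire(3, 25, cdr3_length_range = c(10, 12), seed = 13)
  pos <- sim$pairs
  neg <- generate_negatives(pos, "shuffle", 1.0, seed = 2)
  pairs <- rbind(pos, neg)
  sp <- similarity_split(pos, 0.25, seed = 1)
  sp$train_ids <- c(sp$train_ids, neg$id[seq_len(floor(nrow(neg) * 0.75))])
  sp$test_ids <- c(sp$test_ids, neg$id[-seq_len(floor(nrow(neg) * 0.75))])
  tab <- downsample_experiment(pairs, sp, ratios = c(0.5, 1), seed = 4,
                               k = 2L, dimensions = 16L, epochs = 4,
                               n_trees = 50)
  expect_equal(nrow(tab), 2L)
  expect_true(all(is.finite(tab$auroc)))
  expect_gt(tab$n_train[2], tab$n_train[1])
  tab_again <- downsample_experiment(pairs, sp, ratios = 1, seed = 4,
                                     k = 2L, dimensions = 16L, epochs = 4,
                                     n_trees = 50)
  expect_equal(tab$auroc[2], tab_again$auroc)
})
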