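test_that("tfidf reproduces the worked toy corpus", {
  corpus <- list(d1 = c("a", "a", "b"), d2 = c("a", "c"), d3 = c("c", "c"))
  tab <- tfidf(corpus)
  e <- tab$entries
  a_d1 <- e[e$doc == "d1" & e$token == "a", ]
  expect_equal(a_d1$tf, 2 / 3)
  expect_equal(a_d1$idf, log(3 / 2))
  expect_equal(a_d1$tfidf, (2 / 3) * log(3 / 2), tolerance = 1e-12)
  expect_true(all(e$tfidf == e$tf * e$idf))
  expect_true(all(e$tf > 0 & e$tf <= 1))
  expect_true(all(e$idf >= 0))

  # token present in every document scores zero
  corpus2 <- list(d1 = c("z", "a"), d2 = c("z"), d3 = c("z", "b"))
  e2 <- tfidf(corpus2)$entries
  expect_true(all(e2$tfidf[e2$token == "z"] == 0))

  # min_df drops token b (df = 1)
  e3 <- tfidf(corpus, min_df = 2)$entries
  expect_false("b" %in% e3$token)
  expect_true("a" %in% e3$token)
  expect_error(tfidf(corpus, min_df = 4), "min_df")

  # configurable logarithm base
  e10 <- tfidf(corpus, log_base = 10)$entries
  expect_equal(e10$idf[e10$doc == "d1" & e10$token == "a"], log10(3 / 2))
})

test_that("tfidf matches a brute-force evaluation on random corpora", {
  set.seed(21)
  for (rep in 1:5) {
    corpus <- lapply(seq_len(sample(2:5, 1)), function(i)
      sample(letters[1:6], sample(3:10, 1), replace = TRUE))
    names(corpus) <- paste0("g", seq_along(corpus))
    tab <- tfidf(corpus)$entries
    for (r in seq_len(nrow(tab))) {
      doc <- corpus[[tab$doc[r]]]
      tf <- sum(doc == tab$token[r]) / length(doc)
      df <- sum(vapply(corpus, function(d) tab$token[r] %in% d, logical(1)))
      expect_equal(tab$tfidf[r], tf * log(length(corpus) / df),
                   tolerance = 1e-12)
    }
  }
})

test_that("cluster pooling conserves token counts and skips noise", {
  docs <- list(graph_document(seq_to_graph("GA"), k = 1, id = "s1"),
               graph_document(seq_to_graph("GA"), k = 1, id = "s2"),
               graph_document(seq_to_graph("WY"), k = 1, id = "s3"))
  pooled <- cluster_documents(docs, c(1L, 1L, 0L))
  expect_named(pooled, "1")
  expect_equal(sum(pooled[["1"]]), length(docs[[1]]$tokens) * 2)
  # singleton clusters equal the individual documents
  p2 <- cluster_documents(docs, c(1L, 2L, 0L))
  expect_equal(sum(p2[["1"]]), length(docs[[1]]$tokens))
  expect_equal(p2[["1"]], p2[["2"]])  # identical sequences, identical counts
  expect_error(cluster_documents(docs, c(0L, 0L, 0L)), "no non-noise")
})

test_that("token occurrences map back to centered, padded residue windows", {
  g <- seq_to_graph("ACDEFGHIKL")
  d <- graph_document(g, k = 0)
  # pick a token rooted at residue 4 (glutamate's CA-region labels exist at
  # iteration 0 for every atom of residue 4)
  prov <- d$provenance
  tok4 <- prov$token[prov$root_residue == 4][1]
  w <- token_to_windows(tok4, list(d))
  expect_true(all(nchar(w$window) == 5))
  r4 <- w[w$center == 4, ]
  expect_true(all(r4$window == substr("ACDEFGHIKL", 3, 7)))
  # a window centered at residue 0 is padded on the left
  tok0 <- prov$token[prov$root_residue == 0][1]
  w0 <- token_to_windows(tok0, list(d))
  expect_true(any(startsWith(w0$window, "--")))
  expect_true(all(nchar(w0$window) == 5))
})

test_that("motif selection applies support and exclusivity thresholds", {
  # two clusters of identical-sequence documents: every token is carried by
  # all members of its cluster
  mk_docs <- function(s, n, prefix)
    lapply(seq_len(n), function(i)
      graph_document(seq_to_graph(s), k = 2, id = paste0(prefix, i)))
  docs <- c(mk_docs("CASSAWAGELF", 6, "a"), mk_docs("CASSQQYDTQF", 6, "b"))
  assign <- rep(1:2, each = 6)
  m <- select_motifs(docs, assign, min_tcrs_within = 5,
                     min_total_occurrences = 2, top_tokens = 100)
  expect_s3_class(m, "motif_table")
  expect_gt(nrow(m), 0L)
  expect_true(all(m$support_tcrs >= 5))
  expect_true(all(m$total_occurrences >= m$support_tcrs))
  expect_true(all(nchar(m$window) == 5))
  expect_length(attr(m, "ppm"), nrow(m))
  # support below the within-cluster threshold removes everything
  m2 <- select_motifs(docs, assign, min_tcrs_within = 7,
                      min_total_occurrences = 2)
  expect_equal(nrow(m2), 0L)
  # patterns common to both clusters are non-exclusive and dropped
  docs3 <- c(mk_docs("CASSAWAGELF", 6, "a"), mk_docs("CASSAWAGELF", 6, "b"))
  m3 <- select_motifs(docs3, rep(1:2, each = 6), min_tcrs_within = 5,
                      min_total_occurrences = 2)
  expect_equal(nrow(m3), 0L)
})

test_that("token-level selection recovers a planted motif from epitope pools", {
  sim <- simulate_repertoire(3, 40, cdr3_length_range = c(10, 12),
                             motif_fidelity = 1, seed = 55)
  pos <- sim$pairs
  tcrs <- unique(pos$cdr3)
  truth <- pos$epitope[match(tcrs, pos$cdr3)]
  docs <- lapply(tcrs, function(s) graph_document(seq_to_graph(s), k = 5,
                                                  id = s))
  assign <- as.integer(factor(truth))
  m <- select_motifs(docs, assign, min_tcrs_within = 5,
                     min_total_occurrences = 20)
  for (e in unique(truth)) {
    ci <- as.character(unique(assign[truth == e]))
    expect_true(any(grepl(sim$motifs[[e]], m$window[m$cluster == ci],
                          fixed = TRUE)),
                info = paste("motif", sim$motifs[[e]]))
  }
})

test_that("position probability matrices normalize and respect padding", {
  m <- ppm(c("AGCDE", "AGCDE"))  # identical windows -> one-hot rows
  expect_true(all(rowSums(m) == 1))
  expect_equal(unname(m["0", "C"]), 1)
  m2 <- ppm(c("AGCDE", "TGCDE"))
  expect_equal(unname(m2["-2", c("A", "T")]), c(0.5, 0.5))
  # padding excluded from its position's denominator
  m3 <- ppm(c("--CDE", "A-CDE"))
  expect_equal(unname(m3["-2", "A"]), 1)
  expect_equal(sum(m3["-1", ]), 0)  # only padding at that position
  expect_error(ppm(character(0)), "no windows")
})
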