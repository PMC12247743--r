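# Tabular IO and the top-level pipeline driver.  TSV is the canonical
# format (CSV accepted on read); residue positions are 0-based half-open
# wherever they appear in outputs.

#' Read a CDR3/epitope pairs table
#'
#' The `generic` dialect expects columns `cdr3` and `epitope` (optional
#' `label`, `antigen_group`); the `vdjdb` dialect maps the database's
#' `cdr3` and `antigen.epitope` headers (and `antigen.gene` to the antigen
#' group when present).  Rows containing non-standard residues are dropped
#' and counted in the `dropped` attribute.
#'
#' @param path TSV or CSV file.
#' @param dialect `"generic"` or `"vdjdb"`.
#' @return a [binding_pairs()] data.frame; `attr(, "dropped")` holds the
#'   number of rejected rows.
#' @export
read_pairs <- function(path, dialect = c("generic", "vdjdb")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- data.table::fread(path, data.table = FALSE, showProgress = FALSE)
  if (!nrow(df)) stop("empty pairs file: ", path)
  if (dialect == "vdjdb") {
    if (!all(c("cdr3", "antigen.epitope") %in% names(df)))
      stop("vdjdb dialect requires columns cdr3 and antigen.epitope")
    df$epitope <- df[["antigen.epitope"]]
    if ("antigen.gene" %in% names(df)) df$antigen_group <- df[["antigen.gene"]]
  }
  if (!all(c("cdr3", "epitope") %in% names(df)))
    stop("pairs file must have columns cdr3 and epitope")
  ok_seq <- function(x) !is.na(x) & grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", x)
  valid <- ok_seq(df$cdr3) & ok_seq(df$epitope)
  if (any(!valid))
    warning(sum(!valid), " row(s) with invalid residues dropped (rows: ",
            paste(utils::head(which(!valid), 5), collapse = ", "),
            if (sum(!valid) > 5) ", ..." else "", ")")
  df <- df[valid, , drop = FALSE]
  out <- binding_pairs(df$cdr3, df$epitope,
                       label = if ("label" %in% names(df)) df$label else "positive",
                       antigen_group = if ("antigen_group" %in% names(df))
                         df$antigen_group else NA_character_)
  attr(out, "dropped") <- sum(!valid)
  out
}

#' Write a pairs table
#'
#' @param pairs a `binding_pairs` data.frame.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' Collects every pipeline parameter with its default; the resolved
#' configuration is serialized next to the outputs of every run.
#'
#' @param ... overrides of the defaults listed below.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    wl_iterations = 5L, dimensions = 256L, epochs = 10L,
    negative_samples = 5L, use_edge_labels = FALSE,
    non_attributed = FALSE,
    min_tcrs = 1000L, test_fraction = 0.2, split_group_size = 10L,
    negatives_strategy = "shuffle", negatives_ratio = 1.0,
    n_trees = 500L, max_depth = 0L,
    cluster_min_points = 5L, cluster_metric = "manhattan",
    normalize_embeddings = TRUE,
    eps_min = 0.01, eps_max = 20, eps_points = 50L, pca_dims = 24L,
    motif_min_tcrs = 5L, motif_min_occurrences = 20L, motif_min_df = 1L,
    gap_penalty = 4L, trim_n = 3L, trim_c = 2L,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Run the full pipeline
#'
#' Executes epitope filtering, the similarity-guided split, negative
#' generation (independently per side), pooled graph embedding, random-
#' forest classification, the clustering epsilon sweep on the TCR
#' embeddings, and motif mining on the best-scoring clustering.  All
#' artifacts (split, embeddings, ROC curve, sweep table, motif table,
#' metrics JSON, resolved config) are written under `out_dir`.
#'
#' @param pairs a `binding_pairs` data.frame of positive pairs (a labeled
#'   table may include negatives, which are ignored here and regenerated).
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with `metrics`, `sweep`, `motifs`, `split`.
#' @export
run_pipeline <- function(pairs, config = run_config(), out_dir = tempfile("run")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    message(sprintf("[%s] %s done in %.1fs (seed=%d)", format(Sys.time(), "%H:%M:%S"),
                    name, as.numeric(Sys.time() - t0, units = "secs"),
                    config$seed))
    res
  }

  pos <- pairs[pairs$label == "positive", , drop = FALSE]
  pos <- stage("filter", filter_epitopes(pos, config$min_tcrs))
  if (!nrow(pos)) stop("no epitopes pass filter (min_tcrs = ",
                       config$min_tcrs, ")")

  split <- stage("split", similarity_split(pos, config$test_fraction,
                                           seed = config$seed,
                                           group_size = config$split_group_size))
  tr_pos <- pos[pos$id %in% split$train_ids, , drop = FALSE]
  te_pos <- pos[pos$id %in% split$test_ids, , drop = FALSE]
  neg <- stage("negatives", {
    tr_neg <- generate_negatives(tr_pos, config$negatives_strategy,
                                 config$negatives_ratio, seed = config$seed)
    te_neg <- generate_negatives(te_pos, config$negatives_strategy,
                                 config$negatives_ratio, seed = config$seed + 1L)
    tr_neg$id <- paste0("tr_", tr_neg$id)
    te_neg$id <- paste0("te_", te_neg$id)
    list(train = tr_neg, test = te_neg)
  })
  train <- rbind(tr_pos, neg$train)
  test <- rbind(te_pos, neg$test)

  fc <- feature_config(non_attributed = config$non_attributed)
  em <- stage("embed", embed_sequences(
    unique(c(train$cdr3, test$cdr3, train$epitope, test$epitope)),
    k = config$wl_iterations, dimensions = config$dimensions,
    epochs = config$epochs, seed = config$seed,
    negative_samples = config$negative_samples, config = fc,
    use_edge_labels = config$use_edge_labels, return_documents = TRUE))

  roc <- stage("classify", {
    m <- train_classifier(.pair_feature_matrix(train, em), train$label,
                          n_trees = config$n_trees,
                          max_depth = config$max_depth, seed = config$seed)
    evaluate_auroc(predict_scores(m, .pair_feature_matrix(test, em)),
                   test$label)
  })

  # clustering over the distinct positive TCR embeddings
  tcrs <- unique(pos$cdr3)
  tcr_truth <- vapply(tcrs, function(s)
    pos$epitope[match(s, pos$cdr3)], character(1))
  Xp <- stage("reduce", {
    V <- em$vectors[match(tcrs, em$graph_ids), , drop = FALSE]
    if (config$normalize_embeddings) {
      nrm <- sqrt(rowSums(V^2))
      V <- V / pmax(nrm, .Machine$double.eps)
    }
    reduce_pca(V, n = min(config$pca_dims, length(tcrs), config$dimensions))
  })
  sweep_tab <- stage("cluster", epsilon_sweep(
    Xp, tcr_truth,
    eps_values = exp(seq(log(config$eps_min), log(config$eps_max),
                         length.out = config$eps_points)),
    min_points = config$cluster_min_points,
    metric = config$cluster_metric))

  motifs_tab <- stage("motifs", {
    best_eps <- sweep_tab$epsilon[which.max(sweep_tab$c_csi)]
    best <- dbscan_cluster(stats::dist(Xp, method = config$cluster_metric),
                           cluster_config(best_eps, config$cluster_min_points,
                                          config$cluster_metric))
    docs <- attr(em, "documents")
    tcr_docs <- docs[match(tcrs, vapply(docs, `[[`, character(1), "graph_id"))]
    select_motifs(tcr_docs, best, min_df = config$motif_min_df,
                  min_tcrs_within = config$motif_min_tcrs,
                  min_total_occurrences = config$motif_min_occurrences)
  })

  metrics <- list(auroc = roc$auroc, n_pos = roc$n_pos, n_neg = roc$n_neg,
                  n_train = nrow(train), n_test = nrow(test),
                  best_c_csi = max(sweep_tab$c_csi),
                  best_epsilon = sweep_tab$epsilon[which.max(sweep_tab$c_csi)],
                  n_motifs = nrow(motifs_tab),
                  config = unclass(config))
  utils::write.table(data.frame(id = c(split$train_ids, split$test_ids),
                                side = rep(c("train", "test"),
                                           c(length(split$train_ids),
                                             length(split$test_ids)))),
                     file.path(out_dir, "split.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_embeddings(em, file.path(out_dir, "embeddings.tsv"))
  utils::write.table(roc$curve, file.path(out_dir, "roc_curve.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sweep_tab, file.path(out_dir, "epsilon_sweep.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(motifs_tab), file.path(out_dir, "motifs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(metrics = metrics, sweep = sweep_tab, motifs = motifs_tab,
                 split = split))
}
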