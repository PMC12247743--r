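# Whole-graph embeddings from rooted-subgraph documents: the graph-as-
# document / subgraphs-as-words model, trained with a PV-DBOW objective
# whose softmax over the subgraph vocabulary is estimated by negative
# sampling (see src/doc2vec.cpp).

#' Train graph embeddings over a document corpus
#'
#' Learns one fixed-dimension vector per graph document by maximizing the
#' likelihood of each document's subgraph tokens given its vector.
#' Training is single-threaded and fully deterministic for a given corpus
#' order and seed.
#'
#' @param corpus list of [graph_document()] objects (or lists with at least
#'   `graph_id` and `tokens`).
#' @param dimensions embedding width; the evaluation grid in this field
#'   typically spans 16--512.
#' @param epochs passes over the corpus.
#' @param seed integer seed for the trainer's private RNG.
#' @param negative_samples negatives per positive token (softmax estimator).
#' @param subsample frequent-token subsampling threshold (word2vec rule;
#'   default `1e-4`, the graph2vec reference convention): occurrences of
#'   tokens whose corpus frequency exceeds this are randomly discounted, so
#'   ubiquitous backbone-chemistry tokens do not drown out discriminative
#'   substructure.  `0` disables.
#' @param min_count tokens occurring fewer than this many times in the
#'   corpus are pruned from the vocabulary before training (default 5, the
#'   convention of document-embedding trainers).  Pruning removes
#'   document-unique subgraph tokens so that vectors are shaped by shared
#'   substructure rather than idiosyncratic context.
#' @param alpha,min_alpha linear learning-rate schedule endpoints.
#' @return object of class `embedding_matrix`: list with `graph_ids`,
#'   `vectors` (matrix, one row per graph, rownames = graph_ids),
#'   `dimensions`, `training_meta`, and (for inference) `vocabulary`,
#'   `token_vectors`, `token_counts`.
#' @export
train_embeddings <- function(corpus, dimensions = 256L, epochs = 10L,
                             seed = 1L, negative_samples = 5L,
                             min_count = 5L, subsample = 1e-4,
                             alpha = 0.025, min_alpha = 1e-4) {
  if (!length(corpus)) stop("empty corpus")
  if (dimensions < 1) stop("dimensions must be positive")
  ids <- vapply(corpus, function(d) as.character(d$graph_id), character(1))
  toks <- lapply(corpus, function(d) d$tokens)
  all_tok <- unlist(toks, use.names = FALSE)
  vocab <- unique(all_tok)
  if (min_count > 1L) {
    tot <- table(all_tok)
    vocab <- vocab[tot[vocab] >= min_count]
    if (!length(vocab))  # degenerate tiny corpora: keep everything
      vocab <- unique(all_tok)
  }
  docs <- lapply(toks, function(tt) {
    m <- match(tt, vocab) - 1L
    m[!is.na(m)]
  })
  counts <- tabulate(unlist(docs, use.names = FALSE) + 1L, nbins = length(vocab))
  fit <- doc2vec_dbow(docs, length(vocab), as.integer(counts),
                      as.integer(dimensions), as.integer(epochs),
                      as.integer(negative_samples), alpha, min_alpha,
                      as.integer(seed), subsample)
  vec <- fit$doc_vectors
  rownames(vec) <- ids
  colnames(vec) <- paste0("dim_", seq_len(dimensions) - 1L)
  structure(list(graph_ids = ids, vectors = vec,
                 dimensions = as.integer(dimensions),
                 training_meta = list(dimensions = as.integer(dimensions),
                                      epochs = as.integer(epochs),
                                      seed = as.integer(seed),
                                      negative_samples = as.integer(negative_samples),
                                      min_count = as.integer(min_count),
                                      subsample = subsample,
                                      alpha = alpha, min_alpha = min_alpha),
                 vocabulary = vocab,
                 token_vectors = fit$token_vectors,
                 token_counts = as.integer(counts)),
            class = "embedding_matrix")
}

#' @export
print.embedding_matrix <- function(x, ...) {
  cat("embedding_matrix: ", length(x$graph_ids), " graphs x ",
      x$dimensions, " dimensions\n", sep = "")
  invisible(x)
}

#' Infer a vector for a new document against a trained space
#'
#' Leakage-free alternative to pooled training: token vectors stay frozen
#' and only the new document's vector is optimized.  Tokens unseen during
#' training are dropped.
#'
#' @param em a trained `embedding_matrix`.
#' @param document a [graph_document()].
#' @param epochs,seed inference schedule.
#' @return numeric vector of length `em$dimensions`.
#' @export
infer_embedding <- function(em, document, epochs = 50L, seed = 1L) {
  stopifnot(inherits(em, "embedding_matrix"))
  idx <- match(document$tokens, em$vocabulary) - 1L
  idx <- idx[!is.na(idx)]
  if (!length(idx)) stop("document shares no tokens with the training vocabulary")
  doc2vec_infer(em$token_vectors, as.integer(idx), em$token_counts,
                as.integer(epochs), em$training_meta$negative_samples,
                em$training_meta$alpha, em$training_meta$min_alpha,
                as.integer(seed))
}

#' Embed peptide sequences end to end
#'
#' Convenience composition: sequence -> molecular graph -> WL document ->
#' pooled embedding training.  TCR CDR3s and epitope peptides are embedded
#' in one shared corpus.  Duplicate sequences share one graph construction
#' but receive separate document ids (and therefore separate rows).
#'
#' @param sequences character vector of peptide sequences.
#' @param k WL subtree height (iterations 0..k all contribute tokens).
#' @param dimensions,epochs,seed,negative_samples,min_count,subsample see
#'   [train_embeddings()].
#' @param config a [feature_config()].
#' @param use_edge_labels include bond features in WL descriptors.
#' @param ids optional document ids (default: made unique from sequences).
#' @param return_documents attach the document list as attribute
#'   `"documents"` (needed downstream for motif mining).
#' @return an `embedding_matrix` whose `training_meta` also records
#'   `wl_iterations`.
#' @export
embed_sequences <- function(sequences, k = 5L, dimensions = 256L,
                            epochs = 10L, seed = 1L, negative_samples = 5L,
                            min_count = 5L, subsample = 1e-4,
                            config = feature_config(),
                            use_edge_labels = FALSE, ids = NULL,
                            return_documents = FALSE) {
  if (!length(sequences)) stop("no sequences to embed")
  vapply(sequences, assert_peptide, character(1))
  if (is.null(ids)) ids <- make.unique(sequences, sep = "#")
  if (length(ids) != length(sequences)) stop("ids/sequences length mismatch")
  uniq <- unique(sequences)
  base_docs <- lapply(uniq, function(s)
    graph_document(seq_to_graph(s), k = k, config = config,
                   use_edge_labels = use_edge_labels, id = s))
  names(base_docs) <- uniq
  docs <- mapply(function(s, i) {
    d <- base_docs[[s]]
    d$graph_id <- i
    d
  }, sequences, ids, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  em <- train_embeddings(docs, dimensions = dimensions, epochs = epochs,
                         seed = seed, negative_samples = negative_samples,
                         min_count = min_count, subsample = subsample)
  em$training_meta$wl_iterations <- as.integer(k)
  em$training_meta$non_attributed <- config$non_attributed
  if (return_documents) attr(em, "documents") <- docs
  em
}

#' Write an embedding matrix as TSV plus a JSON metadata sidecar
#'
#' @param em an `embedding_matrix`.
#' @param path output TSV path (columns `id`, `dim_0` ...); the sidecar is
#'   written to `<path>.meta.json`.
#' @return invisibly, `path`.
#' @export
write_embeddings <- function(em, path) {
  stopifnot(inherits(em, "embedding_matrix"))
  df <- data.frame(id = em$graph_ids, em$vectors, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(em$training_meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an embedding matrix written by [write_embeddings()]
#'
#' @param path TSV path.
#' @return an `embedding_matrix` (without trainer state).
#' @export
read_embeddings <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  vec <- as.matrix(df[, -1, drop = FALSE])
  rownames(vec) <- df$id
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path,
                                                          simplifyVector = TRUE)
          else list()
  structure(list(graph_ids = df$id, vectors = vec,
                 dimensions = ncol(vec), training_meta = meta),
            class = "embedding_matrix")
}
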