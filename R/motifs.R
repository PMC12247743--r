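# Cluster-discriminative subgraph motifs: TF-IDF over WL token documents
# pooled per cluster, mapped back to 5-residue sequence windows via the
# token provenance recorded at document time.

#' TF-IDF table over a token corpus
#'
#' `TF(t, g) = count(t in g) / |g|`; `IDF(t, C) = log(|C| / df(t))` with the
#' natural logarithm by default; `TFIDF = TF * IDF`.  Tokens whose document
#' frequency is below `min_df` are dropped, filtering features that are not
#' represented across multiple documents.
#'
#' @param corpus named list mapping document id to a token multiset (a
#'   character vector with repeats, or a named count vector).
#' @param min_df minimum document frequency (default 1 = keep all).
#' @param log_base base of the IDF logarithm (default `exp(1)`).
#' @return list of class `tfidf_table`: `entries` data.frame (doc, token,
#'   count, tf, df, idf, tfidf), `corpus_size`, `min_df`.
#' @export
tfidf <- function(corpus, min_df = 1L, log_base = exp(1)) {
  if (!length(corpus)) stop("empty corpus")
  if (min_df > length(corpus))
    stop("min_df exceeds the corpus size (", length(corpus), ")")
  if (is.null(names(corpus))) names(corpus) <- paste0("doc", seq_along(corpus))
  counts <- lapply(corpus, function(d) {
    if (is.numeric(d)) d else table(d)
  })
  entries <- do.call(rbind, lapply(names(counts), function(g) {
    ct <- counts[[g]]
    data.frame(doc = g, token = names(ct), count = as.numeric(ct),
               tf = as.numeric(ct) / sum(ct), stringsAsFactors = FALSE)
  }))
  df_tab <- table(unique(entries[c("token", "doc")])$token)
  entries$df <- as.numeric(df_tab[entries$token])
  entries <- entries[entries$df >= min_df, , drop = FALSE]
  entries$idf <- log(length(corpus) / entries$df) / log(log_base)
  entries$tfidf <- entries$tf * entries$idf
  rownames(entries) <- NULL
  structure(list(entries = entries, corpus_size = length(corpus),
                 min_df = as.integer(min_df)),
            class = "tfidf_table")
}

#' Pool graph documents by cluster
#'
#' Sums token multiplicities over the member documents of each non-noise
#' cluster, yielding one pooled document per cluster for TF-IDF scoring.
#'
#' @param documents list of [graph_document()] objects, in point order.
#' @param assignments integer cluster ids (0 = noise), one per document, or
#'   a `cluster_result`.
#' @return named list mapping cluster id to a named token-count vector.
#' @export
cluster_documents <- function(documents, assignments) {
  if (inherits(assignments, "cluster_result"))
    assignments <- assignments$assignments
  stopifnot(length(documents) == length(assignments))
  keep <- assignments > 0L
  if (!any(keep)) stop("no non-noise clusters")
  ids <- sort(unique(assignments[keep]))
  out <- lapply(ids, function(ci) {
    toks <- unlist(lapply(documents[assignments == ci], `[[`, "tokens"),
                   use.names = FALSE)
    tab <- table(toks)
    stats::setNames(as.numeric(tab), names(tab))
  })
  stats::setNames(out, as.character(ids))
}

#' Map token occurrences back to 5-residue sequence windows
#'
#' For each occurrence of `token` in the given documents, returns the
#' 5-residue window of the source sequence centered on the root atom's
#' residue (the most informative position, position 0); windows clipped at
#' sequence ends are padded with `'-'`.
#'
#' @param token a WL token string.
#' @param documents list of [graph_document()] objects carrying provenance.
#' @return data.frame with columns `graph_id`, `sequence`, `window`,
#'   `center` (0-based root residue index); one row per occurrence.
#' @export
token_to_windows <- function(token, documents) {
  rows <- lapply(documents, function(d) {
    if (is.null(d$provenance)) stop("document lacks provenance")
    hit <- d$provenance$token == token
    if (!any(hit)) return(NULL)
    centers <- d$provenance$root_residue[hit]
    data.frame(graph_id = d$graph_id, sequence = d$sequence,
               window = vapply(centers, function(ct)
                 .residue_window(d$sequence, ct), character(1)),
               center = centers, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(graph_id = character(0), sequence = character(0),
                      window = character(0), center = integer(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.residue_window <- function(seq, center, flank = 2L) {
  n <- nchar(seq)
  idx <- (center - flank):(center + flank)  # 0-based
  chars <- ifelse(idx < 0L | idx >= n, "-",
                  substring(seq, idx + 1L, idx + 1L))
  paste(chars, collapse = "")
}

#' Select cluster-discriminative sequence motifs
#'
#' Candidate subgraph tokens in each cluster are ranked by their TF-IDF
#' score on the cluster-pooled corpus, then filtered by the selection
#' criteria: present in at least `min_tcrs_within` distinct TCRs of the
#' cluster, in at least `min_total_occurrences` distinct TCRs overall, and
#' (when `exclusive`) not selected for any other cluster.  Each selected
#' pattern is reported as the consensus of its 5-residue occurrence
#' windows (majority residue per position; see [token_to_windows()]), the
#' representation that underlies a sequence logo.  With `level =
#' "window"`, the thresholds are instead applied to literal 5-residue
#' windows, which is only informative when member sequences are highly
#' similar.
#'
#' @param documents list of [graph_document()] objects, in point order.
#' @param assignments cluster ids (0 = noise) or a `cluster_result`.
#' @param min_df,log_base passed to [tfidf()] on the cluster-pooled corpus.
#' @param top_tokens number of top-TF-IDF tokens examined per cluster.
#' @param min_tcrs_within minimum distinct member TCRs carrying the
#'   pattern (default 5).
#' @param min_total_occurrences minimum distinct TCRs carrying the pattern
#'   across the whole input (default 20).
#' @param exclusive drop patterns selected for more than one cluster.
#' @param level `"token"` (default) or `"window"` selection granularity.
#' @return data.frame of class `motif_table`: `cluster`, `window`
#'   (consensus at token level, literal at window level), `token`,
#'   `support_tcrs`, `total_occurrences`, `tfidf`, `exclusive`, sorted by
#'   cluster then decreasing TF-IDF; attribute `"ppm"` holds one position
#'   probability matrix per row.  May have zero rows.
#' @export
select_motifs <- function(documents, assignments, min_df = 1L,
                          log_base = exp(1), top_tokens = 50L,
                          min_tcrs_within = 5L, min_total_occurrences = 20L,
                          exclusive = TRUE, level = c("token", "window")) {
  level <- match.arg(level)
  if (inherits(assignments, "cluster_result"))
    assignments <- assignments$assignments
  pooled <- cluster_documents(documents, assignments)
  tab <- tfidf(pooled, min_df = min(min_df, length(pooled)),
               log_base = log_base)
  empty <- structure(data.frame(cluster = character(0), window = character(0),
                                token = character(0),
                                support_tcrs = integer(0),
                                total_occurrences = integer(0),
                                tfidf = numeric(0), exclusive = logical(0)),
                     class = c("motif_table", "data.frame"))
  # document frequency of every token across ALL input documents (noise
  # included), computed once: `total_occurrences` lookups are O(1)
  doc_df <- table(unlist(lapply(documents, function(d) unique(d$tokens)),
                         use.names = FALSE))
  all_seqs <- vapply(documents, `[[`, character(1), "sequence")
  rows <- list(); ppms <- list()
  for (ci in names(pooled)) {
    e <- tab$entries[tab$entries$doc == ci & tab$entries$tfidf > 0, ,
                     drop = FALSE]
    if (!nrow(e)) next
    e <- utils::head(e[order(-e$tfidf), , drop = FALSE], top_tokens)
    members <- documents[assignments == as.integer(ci)]
    member_seqs <- vapply(members, `[[`, character(1), "sequence")
    for (r in seq_len(nrow(e))) {
      tok <- e$token[r]
      w <- token_to_windows(tok, members)
      if (!nrow(w)) next
      if (level == "token") {
        support <- length(unique(w$graph_id))
        total <- as.integer(doc_df[tok])
        if (support < min_tcrs_within || total < min_total_occurrences) next
        mat <- ppm(w$window)
        cons <- apply(mat, 1, function(p)
          if (all(p == 0)) "-" else colnames(mat)[which.max(p)])
        rows[[length(rows) + 1L]] <- data.frame(
          cluster = ci, window = paste(cons, collapse = ""), token = tok,
          support_tcrs = support, total_occurrences = total,
          tfidf = e$tfidf[r], stringsAsFactors = FALSE)
        ppms[[length(ppms) + 1L]] <- mat
      } else {
        for (win in unique(w$window)) {
          support <- length(unique(w$graph_id[w$window == win]))
          core <- gsub("-", "", win)
          total <- sum(vapply(all_seqs, function(s)
            grepl(core, s, fixed = TRUE), logical(1)))
          if (support < min_tcrs_within || total < min_total_occurrences)
            next
          rows[[length(rows) + 1L]] <- data.frame(
            cluster = ci, window = win, token = tok,
            support_tcrs = support, total_occurrences = total,
            tfidf = e$tfidf[r], stringsAsFactors = FALSE)
          ppms[[length(ppms) + 1L]] <- ppm(w$window[w$window == win])
        }
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  # one row per (cluster, window): keep the best-scoring generating token
  ord <- order(out$cluster, -out$tfidf)
  out <- out[ord, , drop = FALSE]; ppms <- ppms[ord]
  keep <- !duplicated(out[c("cluster", "window")])
  out <- out[keep, , drop = FALSE]; ppms <- ppms[keep]
  key <- if (level == "token") out$token else out$window
  dup <- names(which(table(unique(data.frame(cluster = out$cluster,
                                             key = key))$key) > 1))
  out$exclusive <- !(key %in% dup)
  if (exclusive) { ppms <- ppms[out$exclusive]; out <- out[out$exclusive, , drop = FALSE] }
  rownames(out) <- NULL
  attr(out, "ppm") <- ppms
  structure(out, class = c("motif_table", "data.frame"))
}

#' Position probability matrix of a window set
#'
#' Per-position amino-acid frequencies over 5-residue windows; `'-'`
#' padding is excluded from that position's denominator.  The result
#' underlies a sequence-logo rendering.
#'
#' @param windows character vector of 5-character windows.
#' @return 5 x 20 matrix of probabilities (rows sum to 1 where any residue
#'   is observed); rownames are positions -2..2.
#' @export
ppm <- function(windows) {
  if (!length(windows)) stop("no windows")
  stopifnot(all(nchar(windows) == 5L))
  m <- matrix(0, 5, length(AA_ALPHABET),
              dimnames = list(as.character(-2:2), AA_ALPHABET))
  for (p in 1:5) {
    ch <- substring(windows, p, p)
    ch <- ch[ch != "-"]
    if (!length(ch)) next
    tab <- table(factor(ch, levels = AA_ALPHABET))
    m[p, ] <- as.numeric(tab) / length(ch)
  }
  m
}
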