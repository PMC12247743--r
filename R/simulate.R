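# Synthetic epitope-specific repertoires with planted sequence motifs.
# These emulate the labeled CDR3/epitope tables produced by multiplexed
# antigen-stimulation assays and curated databases, at desk scale, so every
# pipeline stage can be exercised offline.

#' Simulate a labeled epitope-specific repertoire
#'
#' Generates `n_epitopes * tcrs_per_epitope` positive CDR3-epitope pairs.
#' Each epitope gets a distinct random 9-mer peptide and a distinct planted
#' CDR3 motif (default a 3-mer); a `motif_fidelity` fraction of that
#' epitope's CDR3s carry the motif at the central position of the variable
#' core.  CDR3s wear fixed beta-chain-style flanks (`"CASS"` / `"F"`) so
#' N/C-terminal trimming interacts realistically with the planted signal;
#' the remaining positions are uniform over the 20 residues.
#'
#' @param n_epitopes number of epitopes (>= 2).
#' @param tcrs_per_epitope CDR3s per epitope.
#' @param cdr3_length_range min/max total CDR3 length (default c(10, 12):
#'   short beta-chain loops in which the planted motif spans most of the
#'   variable core, emulating the strong within-cluster conservation that
#'   real epitope-specific repertoires derive from biased V/J usage and
#'   clonal relatedness).
#' @param motif_length planted motif length (default 3).
#' @param motifs optional character vector of planted motifs (must be
#'   distinct, one per epitope); random distinct motifs by default.
#' @param motif_fidelity fraction of an epitope's CDR3s carrying its motif
#'   intact (default 0.9).
#' @param prefix,suffix fixed flanks (defaults `"CASS"`, `"F"`).
#' @param seed integer seed; output is deterministic given the seed.
#' @return list with `pairs` (a [binding_pairs()] data.frame, all positive,
#'   with `antigen_group` = epitope), `truth` (data.frame id, cdr3,
#'   epitope, has_motif) and `motifs` (named vector epitope -> motif).
#' @export
simulate_repertoire <- function(n_epitopes = 4L, tcrs_per_epitope = 250L,
                                cdr3_length_range = c(10L, 12L),
                                motif_length = 3L, motifs = NULL,
                                motif_fidelity = 0.9,
                                prefix = "CASS", suffix = "F", seed = 1L) {
  stopifnot(n_epitopes >= 2L, tcrs_per_epitope >= 1L,
            motif_fidelity >= 0, motif_fidelity <= 1)
  rng <- .local_rng(seed + 101L)
  raa <- function(n) AA_ALPHABET[vapply(seq_len(n), function(i)
    rng$int(20L), integer(1))]
  rstr <- function(n) paste(raa(n), collapse = "")
  if (is.null(motifs)) {
    motifs <- character(0)
    while (length(motifs) < n_epitopes) {
      m <- rstr(motif_length)
      if (!(m %in% motifs)) motifs <- c(motifs, m)
    }
  }
  if (anyDuplicated(motifs)) stop("planted motifs must be distinct across epitopes")
  if (length(motifs) != n_epitopes) stop("need one motif per epitope")
  epitopes <- character(0)
  while (length(epitopes) < n_epitopes) {
    e <- rstr(9L)
    if (!(e %in% epitopes)) epitopes <- c(epitopes, e)
  }
  names(motifs) <- epitopes

  min_core <- motif_length
  lo <- max(cdr3_length_range[1], nchar(prefix) + nchar(suffix) + min_core)
  hi <- max(cdr3_length_range[2], lo)
  cdr3 <- epi <- character(n_epitopes * tcrs_per_epitope)
  has_motif <- logical(length(cdr3))
  i <- 0L
  for (e in epitopes) {
    for (t in seq_len(tcrs_per_epitope)) {
      i <- i + 1L
      len <- lo + rng$int(hi - lo + 1L) - 1L
      core_len <- len - nchar(prefix) - nchar(suffix)
      core <- raa(core_len)
      plant <- rng$unif() < motif_fidelity
      if (plant) {
        at <- floor((core_len - motif_length) / 2) + 1L  # central offset
        core[at:(at + motif_length - 1L)] <- strsplit(motifs[[e]], "")[[1]]
      }
      cdr3[i] <- paste0(prefix, paste(core, collapse = ""), suffix)
      epi[i] <- e
      has_motif[i] <- plant
    }
  }
  pairs <- binding_pairs(cdr3, epi, antigen_group = epi)
  list(pairs = pairs,
       truth = data.frame(id = pairs$id, cdr3 = cdr3, epitope = epi,
                          has_motif = has_motif, stringsAsFactors = FALSE),
       motifs = motifs)
}

#' Gaussian-blob embedding testbed
#'
#' Isolates clustering and classifier tests from the embedding trainer:
#' one spherical Gaussian blob per label, centers at mutual Euclidean
#' distance at least `separation`.
#'
#' @param n_points_per_label points per blob.
#' @param n_labels number of blobs.
#' @param separation minimum distance between blob centers.
#' @param noise_sd standard deviation per coordinate.
#' @param dims dimensionality (default `n_labels`).
#' @param seed integer seed.
#' @return list with `X` (matrix) and `labels` (character vector).
#' @export
simulate_embedding_testbed <- function(n_points_per_label = 50L,
                                       n_labels = 4L, separation = 10,
                                       noise_sd = 1, dims = n_labels,
                                       seed = 1L) {
  stopifnot(separation > 0, dims >= n_labels)
  rng <- .local_rng(seed + 211L)
  gauss <- function(n) {  # Box-Muller on the private RNG
    u1 <- vapply(seq_len(n), function(i) max(rng$unif(), 1e-12), numeric(1))
    u2 <- vapply(seq_len(n), function(i) rng$unif(), numeric(1))
    sqrt(-2 * log(u1)) * cos(2 * pi * u2)
  }
  centers <- diag(n_labels) * separation  # mutual distance separation*sqrt(2)
  if (dims > n_labels)
    centers <- cbind(centers, matrix(0, n_labels, dims - n_labels))
  X <- do.call(rbind, lapply(seq_len(n_labels), function(l) {
    pts <- matrix(gauss(n_points_per_label * dims), n_points_per_label, dims)
    sweep(pts * noise_sd, 2, centers[l, ], `+`)
  }))
  list(X = X, labels = rep(paste0("L", seq_len(n_labels)),
                           each = n_points_per_label))
}
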