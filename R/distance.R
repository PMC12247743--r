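# tcrdist-style CDR3 distance: BLOSUM62-derived per-residue cost with a cap,
# N/C-terminal trimming, and center gapping for unequal lengths.

# Standard NCBI BLOSUM62 scores over the 20 residues (alphabetical order),
# embedded so the metric has no runtime dependency; the test suite checks
# every pair against an independently distributed copy of the matrix.
.blosum62_text <- "
A   4  0 -2 -1 -2  0 -2 -1 -1 -1 -1 -2 -1 -1 -1  1  0  0 -3 -2
C   0  9 -3 -4 -2 -3 -3 -1 -3 -1 -1 -3 -3 -3 -3 -1 -1 -1 -2 -2
D  -2 -3  6  2 -3 -1 -1 -3 -1 -4 -3  1 -1  0 -2  0 -1 -3 -4 -3
E  -1 -4  2  5 -3 -2  0 -3  1 -3 -2  0 -1  2  0  0 -1 -2 -3 -2
F  -2 -2 -3 -3  6 -3 -1  0 -3  0  0 -3 -4 -3 -3 -2 -2 -1  1  3
G   0 -3 -1 -2 -3  6 -2 -4 -2 -4 -3  0 -2 -2 -2  0 -2 -3 -2 -3
H  -2 -3 -1  0 -1 -2  8 -3 -1 -3 -2  1 -2  0  0 -1 -2 -3 -2  2
I  -1 -1 -3 -3  0 -4 -3  4 -3  2  1 -3 -3 -3 -3 -2 -1  3 -3 -1
K  -1 -3 -1  1 -3 -2 -1 -3  5 -2 -1  0 -1  1  2  0 -1 -2 -3 -2
L  -1 -1 -4 -3  0 -4 -3  2 -2  4  2 -3 -3 -2 -2 -2 -1  1 -2 -1
M  -1 -1 -3 -2  0 -3 -2  1 -1  2  5 -2 -2  0 -1 -1 -1  1 -1 -1
N  -2 -3  1  0 -3  0  1 -3  0 -3 -2  6 -2  0  0  1  0 -3 -4 -2
P  -1 -3 -1 -1 -4 -2 -2 -3 -1 -3 -2 -2  7 -1 -2 -1 -1 -2 -4 -3
Q  -1 -3  0  2 -3 -2  0 -3  1 -2  0  0 -1  5  1  0 -1 -2 -2 -1
R  -1 -3 -2  0 -3 -2  0 -3  2 -2 -1  0 -2  1  5 -1 -1 -3 -3 -2
S   1 -1  0  0 -2  0 -1 -2  0 -2 -1  1 -1  0 -1  4  1 -2 -3 -2
T   0 -1 -1 -1 -2 -2 -2 -1 -1 -1 -1  0 -1 -1 -1  1  5  0 -2 -2
V   0 -1 -3 -2 -1 -3 -3  3 -2  1  1 -3 -2 -2 -3 -2  0  4 -3 -1
W  -3 -2 -4 -3  1 -2 -2 -3 -3 -2 -1 -4 -4 -2 -3 -3 -2 -3 11  2
Y  -2 -2 -3 -2  3 -3  2 -1 -2 -1 -1 -2 -3 -1 -2 -2 -2 -1  2  7"

.blosum62 <- local({
  lines <- strsplit(trimws(.blosum62_text), "\n")[[1]]
  vals <- lapply(lines, function(l) as.integer(strsplit(trimws(l), "\\s+")[[1]][-1]))
  m <- do.call(rbind, vals)
  aas <- vapply(lines, function(l) substr(trimws(l), 1, 1), character(1))
  dimnames(m) <- list(aas, aas)
  m
})

#' Distance parameters for the CDR3 metric
#'
#' @param gap_penalty cost per gapped position when trimmed lengths differ
#'   (default 4).
#' @param trim_n,trim_c residues removed from the N- and C-terminus before
#'   comparison (defaults 3 and 2, the germline-dominated CDR3 flanks).
#' @param substitution_cap ceiling on the per-residue substitution cost
#'   (default 4).
#' @param weight multiplier applied to the final distance (default 1).
#' @return list of class `distance_params`.
#' @export
distance_params <- function(gap_penalty = 4L, trim_n = 3L, trim_c = 2L,
                            substitution_cap = 4L, weight = 1) {
  stopifnot(gap_penalty >= 0, trim_n >= 0, trim_c >= 0, substitution_cap >= 0)
  structure(list(gap_penalty = as.integer(gap_penalty),
                 trim_n = as.integer(trim_n), trim_c = as.integer(trim_c),
                 substitution_cap = as.integer(substitution_cap),
                 weight = weight),
            class = "distance_params")
}

#' Trim the germline-dominated flanks of a CDR3
#'
#' @param seq CDR3 amino-acid string.
#' @param params a [distance_params()].
#' @return the trimmed sequence.
#' @export
trim_cdr3 <- function(seq, params = distance_params()) {
  assert_peptide(seq)
  n <- nchar(seq)
  if (n <= params$trim_n + params$trim_c)
    stop("sequence '", seq, "' too short to trim ", params$trim_n,
         " N-terminal and ", params$trim_c, " C-terminal residues")
  substr(seq, params$trim_n + 1L, n - params$trim_c)
}

#' Per-residue substitution distance
#'
#' `d(a, b) = min(cap, 4 - BLOSUM62(a, b))`, the published tcrdist
#' convention: identical residues with self-score >= 4 are at distance 0 and
#' dissimilar pairs saturate at the cap.
#'
#' @param a,b one-letter residue codes (vectorized).
#' @param params a [distance_params()].
#' @return integer distance(s).
#' @export
residue_distance <- function(a, b, params = distance_params()) {
  if (any(!(a %in% AA_ALPHABET)) || any(!(b %in% AA_ALPHABET)))
    stop("invalid residue code")
  ifelse(a == b, 0L,
         pmin(params$substitution_cap, 4L - .blosum62[cbind(a, b)]))
}

#' tcrdist-style distance between two CDR3 sequences
#'
#' Both sequences are trimmed, then compared position-wise.  When trimmed
#' lengths differ, the shorter sequence is gapped at its center: the first
#' `ceil(len/2)` positions align from the left, the remainder from the
#' right, and each gapped position costs `gap_penalty` (center ties resolve
#' toward the N-terminal side).  The result is scaled by `weight`.
#'
#' @param s1,s2 CDR3 sequences.
#' @param params a [distance_params()].
#' @return non-negative numeric distance; symmetric in its arguments.
#' @export
cdr3_distance <- function(s1, s2, params = distance_params()) {
  t1 <- strsplit(trim_cdr3(s1, params), "")[[1]]
  t2 <- strsplit(trim_cdr3(s2, params), "")[[1]]
  if (length(t1) > length(t2)) { tmp <- t1; t1 <- t2; t2 <- tmp }
  ls <- length(t1); ll <- length(t2)
  if (ls == ll) {
    d <- sum(residue_distance(t1, t2, params))
  } else {
    left <- ceiling(ls / 2)
    right <- ls - left
    a2 <- c(if (left) t2[seq_len(left)],
            if (right) t2[seq.int(ll - right + 1L, ll)])
    d <- sum(residue_distance(t1, a2, params)) +
      (ll - ls) * params$gap_penalty
  }
  params$weight * d
}

#' Pairwise CDR3 distance matrix
#'
#' @param seqs character vector of CDR3 sequences.
#' @param params a [distance_params()].
#' @return symmetric matrix with zero diagonal, dimnames = `seqs` ids.
#' @export
cdr3_distance_matrix <- function(seqs, params = distance_params()) {
  n <- length(seqs)
  ids <- if (!is.null(names(seqs))) names(seqs) else seqs
  # distances depend only on the trimmed string: compute once per pair of
  # distinct sequences
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1) for (i in seq_len(n - 1)) for (j in seq.int(i + 1L, n)) {
    d <- cdr3_distance(seqs[i], seqs[j], params)
    m[i, j] <- m[j, i] <- d
  }
  m
}

#' Average minimal distance between test and training repertoires
#'
#' For each test CDR3, the minimum distance to any training CDR3 (within the
#' same epitope pool when `per_epitope`), averaged over test sequences.
#' Used to audit how close a held-out set sits to its training set.
#'
#' @param test,train data.frames with columns `cdr3` and (if grouped)
#'   `epitope`; plain character vectors are accepted when `per_epitope` is
#'   `FALSE`.
#' @param per_epitope compute within epitope pools and also return the
#'   per-epitope table.
#' @param params a [distance_params()].
#' @return when `per_epitope = FALSE`, a single number; otherwise a list
#'   with `overall` and a data.frame `per_epitope` (epitope, n_test,
#'   avg_min_distance).
#' @export
avg_min_distance <- function(test, train, per_epitope = FALSE,
                             params = distance_params()) {
  as_df <- function(x) if (is.character(x)) data.frame(cdr3 = x,
                                                       stringsAsFactors = FALSE)
                       else x
  test <- as_df(test); train <- as_df(train)
  if (!nrow(test) || !nrow(train)) stop("both sets must be non-empty")
  min_to_train <- function(te, tr) {
    vapply(te, function(s) min(vapply(tr, function(t)
      cdr3_distance(s, t, params), numeric(1))), numeric(1))
  }
  if (!per_epitope) return(mean(min_to_train(test$cdr3, train$cdr3)))
  eps <- unique(test$epitope)
  missing <- setdiff(eps, unique(train$epitope))
  if (length(missing))
    stop("epitope(s) absent from training side: ", paste(missing, collapse = ", "))
  rows <- lapply(eps, function(e) {
    mins <- min_to_train(test$cdr3[test$epitope == e],
                         train$cdr3[train$epitope == e])
    data.frame(epitope = e, n_test = length(mins),
               avg_min_distance = mean(mins), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  list(overall = sum(tab$avg_min_distance * tab$n_test) / sum(tab$n_test),
       per_epitope = tab)
}
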