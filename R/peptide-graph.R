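#' @useDynLib tcrgraph2vec, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

NODE_FEATURES <- c("atomic_number", "aromaticity", "formal_charge",
                   "hybridization", "degree", "total_hydrogens")
EDGE_FEATURES <- c("bond_type", "aromaticity", "conjugation",
                   "stereochemistry", "ring_membership")

#' Validate a peptide sequence
#'
#' Checks that a sequence is a non-empty string over the 20 standard
#' one-letter amino-acid codes and returns it unchanged.
#'
#' @param seq character scalar, e.g. `"CASSLGQAYEQYF"`.
#' @return the validated sequence (invisibly usable).
#' @export
assert_peptide <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || nchar(seq) < 1L)
    stop("peptide sequence must be a non-empty character scalar")
  bad <- setdiff(strsplit(seq, "")[[1]], AA_ALPHABET)
  if (length(bad))
    stop("invalid residue code(s) in '", seq, "': ",
         paste(unique(bad), collapse = ", "),
         " (alphabet is ", paste(AA_ALPHABET, collapse = ""), ")")
  seq
}

#' Feature configuration for graph attributes
#'
#' Selects which atomic and bond attributes enter the Weisfeiler-Lehman
#' labels.  With `non_attributed = TRUE` the embedding uses graph structure
#' and connectivity only (every atom gets the same starting label); in that
#' case both feature sets must be empty.
#'
#' @param node_features subset of `atomic_number`, `aromaticity`,
#'   `formal_charge`, `hybridization`, `degree`, `total_hydrogens`.
#' @param edge_features subset of `bond_type`, `aromaticity`, `conjugation`,
#'   `stereochemistry`, `ring_membership`.
#' @param non_attributed logical; structure-only labels.
#' @return an object of class `feature_config`.
#' @export
feature_config <- function(node_features = NODE_FEATURES,
                           edge_features = EDGE_FEATURES,
                           non_attributed = FALSE) {
  if (length(node_features))
    node_features <- match.arg(node_features, NODE_FEATURES, several.ok = TRUE)
  if (length(edge_features))
    edge_features <- match.arg(edge_features, EDGE_FEATURES, several.ok = TRUE)
  if (non_attributed && (length(node_features) || length(edge_features))) {
    node_features <- character(0)
    edge_features <- character(0)
  }
  structure(list(node_features = node_features,
                 edge_features = edge_features,
                 non_attributed = non_attributed),
            class = "feature_config")
}

#' Heavy-atom graph of a free amino acid
#'
#' Returns the molecular graph of the free (neutral) amino acid for a
#' one-letter code: nodes are heavy atoms with element, aromaticity, formal
#' charge, hybridization, connectivity degree and implicit-hydrogen count;
#' edges are bonds with type, conjugation, ring membership and stereo.
#' Backbone atoms are tagged `N`, `CA`, `C`, `O` (carbonyl) and
#' `terminal_O` (the carboxyl hydroxyl removed on peptide condensation).
#'
#' @param aa one-letter amino-acid code.
#' @return a `molecular_graph`.
#' @export
residue_template <- function(aa) {
  if (!is.character(aa) || length(aa) != 1L || !(aa %in% AA_ALPHABET))
    stop("unknown residue code '", aa,
         "' (alphabet is ", paste(AA_ALPHABET, collapse = ""), ")")
  seq_to_graph(aa)
}

#' Build the molecular graph of a peptide
#'
#' Converts an amino-acid sequence into a connected heavy-atom graph by
#' joining residue templates N-to-C with peptide-bond condensation: the
#' carboxyl hydroxyl oxygen of residue i is removed and a single conjugated
#' C-N bond is added to residue i+1's backbone nitrogen.  The amide nitrogen
#' loses one hydrogen (proline's loses its only one) and becomes sp2.
#' Node order is residues in sequence order, atoms within a residue in fixed
#' template order, which makes graphs bit-reproducible.
#'
#' @param seq peptide sequence (one-letter codes).
#' @param id identifier stored on the graph (default: the sequence itself).
#' @return an object of class `molecular_graph` with components `nodes`
#'   (data.frame: index, element, aromatic, formal_charge, hybridization,
#'   degree, total_hydrogens, residue_index, backbone_role, atom_name),
#'   `edges` (data.frame: from, to, bond_type, conjugated, in_ring, stereo),
#'   `sequence` and `id`.  Indices are 1-based; `residue_index` is 0-based.
#' @examples
#' g <- seq_to_graph("GG")
#' nrow(g$nodes)  # 9
#' nrow(g$edges)  # 8
#' @export
seq_to_graph <- function(seq, id = seq) {
  assert_peptide(seq)
  res <- strsplit(seq, "")[[1]]
  L <- length(res)

  node_list <- vector("list", L)
  edge_list <- vector("list", L)
  offset <- 0L
  c_prev <- NA_integer_  # node index of previous residue's carbonyl carbon
  for (ri in seq_len(L)) {
    tpl <- .aa_templates[[res[ri]]]
    atoms <- tpl$atoms
    bonds <- tpl$bonds
    if (ri < L) {  # condensation: drop the terminal hydroxyl oxygen
      keep <- atoms$role != "terminal_O"
      drop_name <- atoms$name[!keep]
      atoms <- atoms[keep, , drop = FALSE]
      bonds <- bonds[bonds$a1 != drop_name & bonds$a2 != drop_name, , drop = FALSE]
    }
    if (ri > 1L) {  # amide nitrogen bookkeeping
      n_row <- which(atoms$role == "N")
      atoms$hs[n_row] <- atoms$hs[n_row] - 1L
      atoms$hyb[n_row] <- "sp2"
    }
    idx <- offset + seq_len(nrow(atoms))
    name2idx <- stats::setNames(idx, atoms$name)
    node_list[[ri]] <- data.frame(
      index = idx,
      element = atoms$element,
      aromatic = atoms$aromatic,
      formal_charge = atoms$charge,
      hybridization = atoms$hyb,
      degree = 0L,
      total_hydrogens = atoms$hs,
      residue_index = ri - 1L,
      backbone_role = atoms$role,
      atom_name = atoms$name,
      stringsAsFactors = FALSE)
    ed <- data.frame(
      from = unname(name2idx[bonds$a1]),
      to = unname(name2idx[bonds$a2]),
      bond_type = bonds$type,
      conjugated = bonds$conjugated,
      in_ring = bonds$ring,
      stereo = "none",
      stringsAsFactors = FALSE)
    if (ri > 1L)  # the peptide bond itself
      ed <- rbind(data.frame(from = c_prev, to = unname(name2idx[["N"]]),
                             bond_type = "single", conjugated = TRUE,
                             in_ring = FALSE, stereo = "none",
                             stringsAsFactors = FALSE), ed)
    edge_list[[ri]] <- ed
    c_prev <- unname(name2idx[["C"]])
    offset <- offset + nrow(atoms)
  }
  nodes <- do.call(rbind, node_list)
  edges <- do.call(rbind, edge_list)
  rownames(nodes) <- rownames(edges) <- NULL
  deg <- tabulate(c(edges$from, edges$to), nbins = nrow(nodes))
  nodes$degree <- as.integer(deg)
  structure(list(nodes = nodes, edges = edges, sequence = seq, id = id),
            class = "molecular_graph")
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat("molecular_graph '", x$id, "': ", nchar(x$sequence), " residues, ",
      nrow(x$nodes), " atoms, ", nrow(x$edges), " bonds\n", sep = "")
  invisible(x)
}

#' Summary census of a molecular graph
#'
#' @param g a `molecular_graph`.
#' @return list with `nodes`, `edges`, `rings` (edges - nodes + 1 for the
#'   connected peptide graph), `aromatic_atoms` and `elements` (named count
#'   per element symbol).
#' @export
graph_census <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  symbols <- c(`6` = "C", `7` = "N", `8` = "O", `16` = "S")
  el <- table(symbols[as.character(g$nodes$element)])
  list(nodes = nrow(g$nodes),
       edges = nrow(g$edges),
       rings = nrow(g$edges) - nrow(g$nodes) + 1L,
       aromatic_atoms = sum(g$nodes$aromatic),
       elements = stats::setNames(as.integer(el), names(el)))
}

#' Export a molecular graph as node and edge tables
#'
#' Writes two TSV files with stable column names for external inspection.
#'
#' @param g a `molecular_graph`.
#' @param node_path,edge_path output file paths.
#' @return invisibly, the paths.
#' @export
write_graph_tsv <- function(g, node_path, edge_path) {
  stopifnot(inherits(g, "molecular_graph"))
  utils::write.table(g$nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(g$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(node_path, edge_path))
}
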