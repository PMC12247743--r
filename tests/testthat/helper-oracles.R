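# Independent oracles used across the suite.

# --- cheminformatics-toolkit oracle -----------------------------------------
# Builds peptide molecules with RDKit (via the system Python) and reports,
# per sequence: heavy-atom count, bond count, aromatic-atom count, sorted
# element multiset and sorted degree sequence.  Entirely independent of the
# package's template-based construction.

rdkit_available <- local({
  ok <- NULL
  function() {
    if (is.null(ok)) {
      ok <<- nzchar(Sys.which("python")) &&
        system2("python", c("-c", shQuote("import rdkit")),
                stdout = FALSE, stderr = FALSE) == 0
    }
    ok
  }
})

rdkit_census <- function(seqs) {
  infile <- tempfile(fileext = ".txt")
  outfile <- tempfile(fileext = ".json")
  writeLines(seqs, infile)
  script <- '
import sys, json
from rdkit import Chem
out = []
for line in open(sys.argv[1]):
    seq = line.strip()
    m = Chem.MolFromSequence(seq)
    deg = sorted(a.GetDegree() for a in m.GetAtoms())
    els = sorted(a.GetAtomicNum() for a in m.GetAtoms())
    out.append({"seq": seq, "nodes": m.GetNumAtoms(), "edges": m.GetNumBonds(),
                "aromatic": sum(a.GetIsAromatic() for a in m.GetAtoms()),
                "elements": els, "degrees": deg})
json.dump(out, open(sys.argv[2], "w"))
'
  scr <- tempfile(fileext = ".py")
  writeLines(script, scr)
  status <- system2("python", c(scr, infile, outfile),
                    stdout = FALSE, stderr = FALSE)
  stopifnot(status == 0)
  jsonlite::read_json(outfile, simplifyVector = TRUE)
}

# --- brute-force DBSCAN oracle ----------------------------------------------
# Direct implementation of the printed definitions: core points by
# neighborhood size, clusters as connected components of the core-core
# epsilon graph (numbered by first core in input order), border points
# attached to the lowest-numbered cluster among their core neighbors.

brute_dbscan <- function(D, eps, m) {
  n <- nrow(D)
  core <- vapply(seq_len(n), function(i) sum(D[i, ] <= eps) >= m, logical(1))
  assign <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || assign[i] != 0L) next
    cl <- cl + 1L
    # component of core points density-connected to i via chains of cores
    comp <- i
    repeat {
      grow <- which(core & assign == 0L & !(seq_len(n) %in% comp) &
                    vapply(seq_len(n), function(q)
                      any(D[q, comp] <= eps), logical(1)))
      if (!length(grow)) break
      comp <- c(comp, grow)
    }
    assign[comp] <- cl
  }
  for (i in seq_len(n)) {
    if (core[i] || assign[i] != 0L) next
    nbc <- which(core & D[i, ] <= eps)
    if (length(nbc)) assign[i] <- min(assign[nbc])
  }
  assign
}

# --- brute-force auROC ------------------------------------------------------
brute_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# --- misc helpers -----------------------------------------------------------
random_peptides <- function(n, max_len = 15L, min_len = 1L, seed = 1L) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    L <- sample(min_len:max_len, 1)
    paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], L,
                 replace = TRUE), collapse = "")
  }, character(1))
}

# Permute the node indices of a molecular_graph (graph isomorphism under
# relabeling), for WL invariance checks.
permute_graph <- function(g, perm) {
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  nodes <- g$nodes[perm, , drop = FALSE]
  nodes$index <- seq_along(perm)
  edges <- g$edges
  edges$from <- inv[edges$from]
  edges$to <- inv[edges$to]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges, sequence = g$sequence,
                 id = g$id), class = "molecular_graph")
}
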