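# Weisfeiler-Lehman relabeling over molecular graphs and the rooted-subgraph
# "documents" consumed by the graph embedding trainer.  Iteration-0 labels
# serialize the enabled node features; each further iteration hashes a
# node's current label together with the sorted multiset of its neighbors'
# descriptors, so the label at iteration t encodes the t-hop neighborhood.

.serialize_nodes <- function(g, config) {
  if (config$non_attributed) return(rep("x", nrow(g$nodes)))
  n <- g$nodes
  parts <- list(atomic_number = paste0("an", n$element),
                aromaticity = paste0("ar", as.integer(n$aromatic)),
                formal_charge = paste0("fc", n$formal_charge),
                hybridization = paste0("hy", n$hybridization),
                degree = paste0("dg", n$degree),
                total_hydrogens = paste0("th", n$total_hydrogens))
  keep <- NODE_FEATURES[NODE_FEATURES %in% config$node_features]
  if (!length(keep)) return(rep("x", nrow(n)))
  do.call(paste, c(parts[keep], sep = ";"))
}

.serialize_edges <- function(g, config) {
  if (config$non_attributed || !length(config$edge_features))
    return(rep("", nrow(g$edges)))
  e <- g$edges
  parts <- list(bond_type = paste0("bt", e$bond_type),
                aromaticity = paste0("ba", as.integer(e$bond_type == "aromatic")),
                conjugation = paste0("cj", as.integer(e$conjugated)),
                stereochemistry = paste0("st", e$stereo),
                ring_membership = paste0("rg", as.integer(e$in_ring)))
  keep <- EDGE_FEATURES[EDGE_FEATURES %in% config$edge_features]
  do.call(paste, c(parts[keep], sep = ";"))
}

#' Iteration-0 Weisfeiler-Lehman labels
#'
#' Each node's starting label is a canonical serialization of the node
#' features enabled in `config`; with `non_attributed = TRUE` (or an empty
#' feature set) every node receives the same constant token so only graph
#' structure enters subsequent iterations.
#'
#' @param g a `molecular_graph`.
#' @param config a [feature_config()].
#' @return character vector of labels, one per node.
#' @export
initial_labels <- function(g, config = feature_config()) {
  stopifnot(inherits(g, "molecular_graph"), inherits(config, "feature_config"))
  .serialize_nodes(g, config)
}

#' One Weisfeiler-Lehman refinement step
#'
#' Produces the next labeling: each node's new label is a stable 128-bit
#' digest of its current label concatenated with the lexicographically
#' sorted multiset of neighbor descriptors.  A descriptor is the neighbor's
#' current label, optionally prefixed by the serialized features of the
#' connecting bond when `use_edge_labels` is on.
#'
#' @param g a `molecular_graph`.
#' @param labels character vector, current labels (one per node).
#' @param use_edge_labels logical; include bond features in descriptors.
#' @param config a [feature_config()] supplying the edge-feature subset.
#' @return character vector of refined labels.
#' @export
wl_iterate <- function(g, labels, use_edge_labels = FALSE,
                       config = feature_config()) {
  stopifnot(length(labels) == nrow(g$nodes))
  from <- c(g$edges$from, g$edges$to)
  to <- c(g$edges$to, g$edges$from)
  desc <- labels[to]
  if (use_edge_labels) {
    ed <- .serialize_edges(g, config)
    desc <- paste0(c(ed, ed), "~", desc)
  }
  ord <- order(from, desc, method = "radix")
  nb <- vapply(split(desc[ord], factor(from[ord], levels = seq_along(labels))),
               paste, character(1), collapse = ",")
  fnv128_hex(paste0(labels, "|", nb))
}

#' Full WL labeling for iterations 0..k
#'
#' @inheritParams wl_iterate
#' @param k subtree height (number of refinement iterations, >= 0).
#' @return object of class `wl_labeling`: list with `labels` (list of k+1
#'   character vectors) and `k`.
#' @export
wl_labeling <- function(g, k = 5L, config = feature_config(),
                        use_edge_labels = FALSE) {
  stopifnot(k >= 0)
  labs <- vector("list", k + 1L)
  labs[[1L]] <- initial_labels(g, config)
  if (k > 0) for (t in seq_len(k))
    labs[[t + 1L]] <- wl_iterate(g, labs[[t]], use_edge_labels, config)
  structure(list(labels = labs, k = as.integer(k)), class = "wl_labeling")
}

#' Rooted-subgraph document of a graph
#'
#' Treats the graph as a document whose words are the WL rooted-subgraph
#' tokens of every node at every iteration 0..k, giving exactly
#' `|V| * (k+1)` tokens.  Provenance records, per token occurrence, the root
#' node, the root atom's residue index and the contiguous residue interval
#' reached by the t-hop neighborhood (atoms only bond within a residue or to
#' adjacent residues, so the reached set is an interval).
#'
#' @inheritParams wl_labeling
#' @param id document identifier (default the graph id).
#' @return object of class `graph_document`: list with `graph_id`, `tokens`
#'   (character vector), `provenance` (data.frame: token, iteration, root,
#'   root_residue, res_min, res_max) and `sequence`.
#' @export
graph_document <- function(g, k = 5L, config = feature_config(),
                           use_edge_labels = FALSE, id = g$id) {
  wl <- wl_labeling(g, k, config, use_edge_labels)
  nV <- nrow(g$nodes)
  res <- g$nodes$residue_index
  # residue interval reached by the t-hop ball around each node
  from <- c(g$edges$from, g$edges$to)
  to <- c(g$edges$to, g$edges$from)
  rmin <- rmax <- res
  fr <- factor(from, levels = seq_len(nV))
  tok <- vector("list", k + 1L)
  pmin_l <- pmax_l <- vector("list", k + 1L)
  for (t in 0:k) {
    if (t > 0) {
      rmin <- pmin(rmin, as.integer(tapply(rmin[to], fr, min)))
      rmax <- pmax(rmax, as.integer(tapply(rmax[to], fr, max)))
    }
    tok[[t + 1L]] <- wl$labels[[t + 1L]]
    pmin_l[[t + 1L]] <- rmin
    pmax_l[[t + 1L]] <- rmax
  }
  prov <- data.frame(token = unlist(tok, use.names = FALSE),
                     iteration = rep(0:k, each = nV),
                     root = rep.int(seq_len(nV), k + 1L),
                     root_residue = rep.int(res, k + 1L),
                     res_min = unlist(pmin_l, use.names = FALSE),
                     res_max = unlist(pmax_l, use.names = FALSE),
                     stringsAsFactors = FALSE)
  structure(list(graph_id = id, tokens = prov$token, provenance = prov,
                 sequence = g$sequence),
            class = "graph_document")
}
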