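---
title: "Atomic-level graph embeddings of TCR repertoires: models, parameters and design choices"
author: "tcrgraph2vec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atomic-level graph embeddings of TCR repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models implemented by `tcrgraph2vec`, the
parameters that matter, and the design decisions taken where the method
left genuine freedom.  Nothing here asserts an empirical result that the
package's tests and `scripts/acceptance.R` do not themselves compute.

## 1. From sequence to molecular graph

A peptide (a TCR β-chain CDR3 loop or an antigenic epitope) is converted to
a connected heavy-atom graph by joining per-residue templates N-to-C with
peptide-bond condensation: the carboxyl hydroxyl oxygen of residue *i* is
removed, a single conjugated C–N bond is added to residue *i+1*'s backbone
nitrogen, the amide nitrogen loses one hydrogen (proline its only one) and
becomes sp2.  Nodes carry element, aromaticity, formal charge,
hybridization, heavy-atom degree and implicit hydrogen count; edges carry
bond type, conjugation, ring membership and stereo.

Choices the chemistry leaves open, and what we do:

* **Hydrogens are not nodes.**  They are bookkept per atom
  (`total_hydrogens`), the heavy-atom convention implied by listing the
  hydrogen count as a node *feature*.
* **Neutral protonation everywhere.**  Free N-terminal amine, free
  C-terminal carboxylic acid, uncharged side chains (Lys, Arg, Asp, Glu,
  His).  Protonation equilibria are out of scope; the formal-charge field
  exists so attributed labels remain configuration-complete.
* **Aromaticity.**  His, Phe, Tyr and Trp rings are aromatic with aromatic
  bond type; hybridization is sp2 for aromatic and carbonyl atoms, sp3
  otherwise.
* **Stereo is uniformly `none`.**  Linear peptides built from sequence
  carry no E/Z annotation; the field is retained so the edge-feature
  configuration space is complete.
* **Determinism.**  Residues appear in sequence order and atoms in a fixed
  template order (PDB convention, terminal hydroxyl last), so identical
  sequences give bit-identical graphs.

The test suite cross-checks node/edge counts, element multisets,
aromatic-atom counts and degree sequences against an independent
cheminformatics toolkit for all twenty residues and one hundred random
peptides, and verifies the poly-glycine law (nodes = 4L+1, edges = 4L).

## 2. Weisfeiler-Lehman documents

Iteration-0 labels serialize the enabled node features (a single constant
token in the non-attributed, structure-only configuration).  One refinement
replaces a node's label with a stable 128-bit FNV-1a digest of its current
label plus the lexicographically sorted multiset of neighbor descriptors; a
descriptor optionally prefixes the serialized bond features of the
connecting edge.  The document of a graph contains the labels of **all**
nodes at **all** iterations 0..k, hence exactly |V|·(k+1) tokens; this
keeps k = 0 meaningful and matches standard Graph2Vec practice.

Two decisions deserve emphasis:

* **Hash stability.**  Tokens are digests of canonical serializations,
  never process-salted hashes, so documents — and therefore TF-IDF
  vocabularies and motif tables — are reproducible across runs, machines
  and sessions.
* **Edge features enter through neighbor descriptors.**  The feature list
  names bond attributes without fixing how they reach the kernel;
  prefixing the descriptor is the declared mechanism and can be switched
  off (`use_edge_labels = FALSE`, the default).

Every token occurrence records provenance: its root node, the root's
residue index, and the residue interval reached by the t-hop ball (atoms
bond only within a residue or to adjacent residues, so the reached set is
always an interval).  Provenance is what lets motif mining map subgraph
tokens back onto sequence windows.

## 3. The embedding trainer

Graphs-as-documents are embedded with PV-DBOW: each document vector is
trained to predict its own tokens, the softmax over the subgraph
vocabulary estimated by negative sampling (5 negatives per positive).  The
trainer is compiled, single-threaded, and uses a private xorshift RNG, so
a given (corpus order, seed) reproduces vectors bitwise.

Defaults, with units and rationale:

| parameter | default | why |
|---|---|---|
| `k` (WL height) | 5 | intermediate heights balance context against overfitting; the classification grid in the field spans 1–10 |
| `dimensions` | 256 | the upper-middle of the 16–512 evaluation grid; desk-scale analyses in this package use 64 |
| `epochs` | 10 | sufficient for convergence at desk scale; more epochs overfit document vectors to idiosyncratic tokens |
| `negative_samples` | 5 | the standard estimator count |
| `min_count` | 5 | vocabulary pruning convention of document-embedding trainers; removes document-unique subgraph tokens |
| `subsample` | 1e-4 | frequent-token subsampling, the Graph2Vec reference convention; without it, ubiquitous backbone-chemistry tokens dominate the gradient mass |
| `alpha` → `min_alpha` | 0.025 → 1e-4 | linear word2vec-style decay |

Pooled joint training over all sequences (TCRs **and** epitopes in one
corpus) is the default, matching the pooled design of the method this
package implements.  Pooling lets held-out graphs influence the embedding
space — a transductive caveat — so an inference mode with frozen token
vectors (`infer_embedding()`) is provided for strictly inductive use.

## 4. Classification

Binding pairs are represented by concatenating the TCR and epitope vectors
(TCR first, length 2d) and classified with a random forest (500 trees,
unlimited depth, single-threaded, seeded).  Evaluation is auROC computed
as the Mann-Whitney rank statistic with ties counted one half; the test
suite pins it to brute-force enumeration of positive–negative pairs.

The 80/20 split is similarity-guided rather than random: within each
epitope group, random seed TCRs and their exact nearest neighbors (L2 on
one-hot encodings, neighbor groups of 10) go to the test side until the
20% quota is met.  Assignment operates on distinct CDR3 strings, so an
identical string can never appear on both sides, and pair-level
disjointness is guaranteed by construction.  Exact k-NN replaces the
approximate-search library used at repertoire scale — same contract, no
approximation error.  Negatives (1:1 with positives by default; the ratio
was unstated, so it is a parameter) are generated **after** the split,
independently per side, pairing TCRs with non-cognate epitopes
(`shuffle`) or with epitopes from other antigen groups (`swap_groups`);
generating them before the split would let one negative's TCR leak across
sides.

## 5. Clustering and its metrics

TCR embeddings are L2-normalized, reduced to 24 principal components, and
clustered with DBSCAN under the Manhattan metric across a log-spaced ε
sweep (0.01–20, 50 points).  Normalization is our addition: PV-DBOW vector
norms track document length and token frequency while direction carries
content, and clustering unnormalized vectors mixes the two.  `min_points`
defaults to 5 (the source method never states it); the ε-neighborhood
includes the point itself, following the printed definition of a core
point; border points join the first discovered cluster, with discovery
order fixed by input order for determinism.  Distance-matrix inputs (e.g.
precomputed CDR3 distances) go through classical MDS instead of PCA.

c-Precision is the size-weighted mean over clusters of the best label
overlap fraction (the unweighted mean is also reported, since the
aggregation was unstated).  c-CSI divides total best-overlaps by (total
clustered + total labeled − total best-overlaps); noise points appear only
in the label total, the one reading under which the metric rewards "the
proportion of well-clustered points".

## 6. Motif mining

Documents of cluster members are pooled (multiplicities summed) into one
document per cluster; TF-IDF uses the natural logarithm (the formula's
"log" is unqualified; the base is configurable) and a minimum document
frequency filter (default 1 — cluster-pooled corpora are small, and a
pool-specific token has df = 1 by design).  Selection applies the
published criteria — high TF-IDF rank, presence in ≥ 5 member TCRs,
≥ 20 TCRs overall, cross-cluster exclusivity — at the **token** level, and
reports each selected subgraph pattern as the consensus of its 5-residue
occurrence windows (centered on the root residue, `'-'`-padded at the
termini and excluded from PPM denominators).  The alternative reading —
thresholding literal 5-mer windows — is retained (`level = "window"`) but
is only informative when member sequences are nearly identical: over a
variable background a specific 5-mer containing a 3-residue motif recurs
with probability ~(1/20)² per sequence, so literal windows cannot
accumulate support.  "Most informative position" is operationalized as the
WL root residue.

## 7. The synthetic repertoire generator

The generator emulates an epitope-annotated repertoire: each of
`n_epitopes` epitopes receives a distinct random 9-mer peptide and a
distinct planted 3-mer CDR3 motif; `motif_fidelity` (default 0.9) of that
epitope's CDR3s carry the motif at the center of the variable core;
flanks are fixed (`CASS`/`F`) so N/C-terminal trimming interacts
realistically with the planted signal; all other positions are uniform
over the 20 residues.  CDR3 lengths default to 10–12: short loops in which
the planted motif spans most of the variable core.  Real repertoires
center nearer 14–15 residues, but their epitope-specific clusters share
far more than an isolated 3-mer (biased V/J usage, clonal relatedness,
near-identical loops); with a uniform background, the only way a 3-mer
can dominate the loop — the "well-separated" regime the generator is
meant to produce — is for the loop to be short.  What passing tests on
this generator show is that the pipeline recovers planted signal under
idealized conditions; they do not certify performance on real
repertoires, whose conservation structure, length distributions and
assay noise the generator does not model.

## 8. Numerical choices and degenerate inputs

* Tokens: 128-bit FNV-1a over canonical serializations; vocabulary order
  is first-appearance order, fixed by corpus order.
* The trainer falls back to the unpruned vocabulary when pruning would
  empty a (tiny) corpus; inference drops tokens unseen in training and
  errors only if nothing remains.
* DBSCAN with ε below the smallest pairwise distance yields all-noise
  (c-Precision undefined and reported as `NA`; c-CSI 0); ε above the
  diameter yields one cluster.
* MDS pads with zero coordinates when the spectrum supplies fewer
  positive eigenvalues than requested dimensions.
* CDR3s shorter than `trim_n + trim_c + 1` are rejected, never silently
  truncated; unequal trimmed lengths are center-gapped with ties toward
  the N-terminal side.
* Simulation, splitting and negative generation use a private
  Lehmer RNG, so package calls neither perturb nor depend on the caller's
  `.Random.seed`.

## 9. Problem sizes

Desk-scale analyses in the tests and the acceptance script use 4 epitopes
× 250 TCRs (≈1,000 graphs of ~80 atoms), WL height 5, 64 dimensions and
three simulation replicates — small enough to run in minutes on one core
while exercising every stage at realistic vocabulary sizes (~10⁵ subgraph
tokens).  The depth filter (≥ 1,000 TCRs per epitope at repertoire scale)
is a parameter (`min_tcrs`) and is set to 100 at desk scale.

## 10. Known limitations

* β-chain CDR3 only; no α-chain, V/J context, or MHC restriction.
* Pooled (transductive) embedding by default; the inductive mode exists
  but was not the primary evaluation path.
* Density-based clustering under a single global radius fragments clouds
  of varying density; on the synthetic benchmark the embeddings separate
  epitopes (5-NN label accuracy ≈ 0.94 in the diagnostic runs reproduced
  by the acceptance script's conditions) better than any single-ε DBSCAN
  clustering can report, which is why reported c-CSI values sit well
  below cluster purity.
* The per-residue distance is the published capped-BLOSUM62 convention;
  the full multi-CDR weighting scheme of its source method is out of
  scope (weight exposed as a parameter, default 1).
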