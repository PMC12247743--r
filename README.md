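# tcrgraph2vec

Atomic-level graph embeddings for T-cell receptor (TCR) antigen-specificity
analysis.

Recognition of peptide–MHC complexes by TCRs drives adaptive immunity, and
predicting which TCRs bind which antigenic peptides from sequence alone
remains hard: the β-chain CDR3 loop that dominates peptide contact is
hypervariable, and sequence-level encodings (one-hot, k-mers, language-model
embeddings) miss the local biophysical structure of short loops.  This
package represents both CDR3s and epitope peptides as **heavy-atom molecular
graphs** — atoms as nodes with chemical attributes, bonds as edges — and
learns fixed-dimension whole-graph embeddings from **Weisfeiler-Lehman (WL)
rooted-subgraph documents**, the Graph2Vec construction.  The embeddings
feed three analyses:

1. **Binding classification** — a random forest on concatenated
   (TCR, epitope) embedding pairs, evaluated by auROC on a
   similarity-guided, leakage-controlled 80/20 split;
2. **Repertoire clustering** — DBSCAN over an ε sweep (Manhattan metric,
   PCA to 24 dimensions), scored against epitope labels with the purity
   metrics c-Precision and c-CSI;
3. **Motif mining** — TF-IDF scoring of WL subgraph tokens per cluster,
   mapped back to 5-residue sequence windows through per-token residue
   provenance.

It is aimed at computational immunologists working with epitope-annotated
repertoires (multiplexed antigen-stimulation assays, VDJdb-style tables).

## The model

Each graph `G` is treated as a document whose words are the WL labels of
every node at iterations `0..k`: the iteration-0 label serializes the
enabled atomic features (element, aromaticity, formal charge,
hybridization, degree, hydrogen count), and each refinement hashes a node's
label with the sorted multiset of its neighbors' labels, so iteration `t`
encodes the `t`-hop neighborhood:

    BoW(G) = Σ_{u ∈ V} φ(h(u))

A document-embedding model (PV-DBOW) learns one vector `v(G)` per graph by
maximizing `Π P(h_j | v(G_i))`, the softmax over the subgraph vocabulary
estimated by negative sampling.  Clusterings are scored with

    c-Precision(C_i) = max_j |C_i ∩ L_j| / |C_i|
    c-CSI = Σ_i max_j |C_i ∩ L_j| / (Σ_i |C_i| + Σ_j |L_j| − Σ_i max_j |C_i ∩ L_j|)

where `L_j` are the epitope label groups; unclustered (noise) points count
in `Σ|L_j|` only, so c-CSI penalizes both impurity and failure to cluster.
Subgraph motifs are ranked per cluster by `TF-IDF(t,g,C) = TF(t,g) ×
ln(|C|/df(t))`.  A tcrdist-style CDR3 metric (BLOSUM62-derived residue
costs capped at 4, gap penalty 4, trimming 3 N-/2 C-terminal residues) is
included for repertoire audits.

A synthetic-repertoire generator plants per-epitope 3-mer motifs in
CDR3-like sequences (`CASS…F` flanks), so the complete pipeline is testable
without any external downloads.

## Worked example

```r
library(tcrgraph2vec)

# a 4-epitope x 100-TCR repertoire with planted central 3-mers
sim <- simulate_repertoire(n_epitopes = 4, tcrs_per_epitope = 100, seed = 42)
sim$motifs
#> GSPEIGTFL WPIWLNQQA VGDPMWMTR IETRTKMFK
#>     "AEY"     "MKD"     "PWN"     "HTD"

g <- seq_to_graph("CASSLGQAYEQYF")
g
#> molecular_graph 'CASSLGQAYEQYF': 13 residues, 103 atoms, 105 bonds
cdr3_distance("CASSLGQAYEQYF", "CASSIGQAYEQYF")
#> [1] 2

cfg <- run_config(min_tcrs = 50L, dimensions = 64L, seed = 42L)
res <- run_pipeline(sim$pairs, cfg, "out/")
res$metrics$auroc        # 1     : planted binding signal fully recovered
res$metrics$best_c_csi   # 0.723 : best clustering quality over the eps sweep
```

Test auROC of 1 means every held-out positive pair outscored every
generated negative; c-CSI 0.723 means most TCRs landed in epitope-pure
DBSCAN clusters at the best radius.  Motif mining over the epitope pools
recovers the planted 3-mers as the centers of its consensus windows:

```r
tcrs  <- unique(sim$pairs$cdr3)
truth <- sim$pairs$epitope[match(tcrs, sim$pairs$cdr3)]
docs  <- lapply(tcrs, function(s) graph_document(seq_to_graph(s), k = 5, id = s))
mo <- select_motifs(docs, as.integer(factor(truth)),
                    min_tcrs_within = 5, min_total_occurrences = 20)
head(as.data.frame(mo)[, c("cluster", "window", "support_tcrs")], 4)
#>   cluster window support_tcrs
#> 1       1  MAEYA           89
#> 2       1  MAEYQ           84
#> 3       1  SMAEY           65
#> 4       1  AEYQF           63
```

`run_pipeline()` writes the split, embeddings, ROC curve, ε-sweep table,
motif table, metrics JSON and the resolved configuration under `out/`.  A
command-line driver with subcommands (`simulate`, `embed`, `classify`,
`cluster`, `motifs`, `distance`, `run`) is installed at
`inst/cli/tcrgraph2vec.R`.

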