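test_that("single-residue templates match the worked atom/bond counts", {
  g <- residue_template("G")
  expect_equal(nrow(g$nodes), 5L)
  expect_equal(nrow(g$edges), 4L)
  expect_setequal(g$nodes$backbone_role,
                  c("N", "CA", "C", "O", "terminal_O"))

  a <- residue_template("A")
  expect_equal(nrow(a$nodes), 6L)
  expect_equal(nrow(a$edges), 5L)

  f <- residue_template("F")
  expect_equal(sum(f$nodes$aromatic), 6L)
  expect_equal(sum(f$edges$bond_type == "aromatic"), 6L)
  # one benzene ring: edges = nodes - 1 + 1
  expect_equal(nrow(f$edges), nrow(f$nodes))

  expect_error(residue_template("X"), "unknown residue")
  expect_error(residue_template("B"), "unknown residue")
})

test_that("every residue template has exactly one CA and non-negative hydrogens", {
  for (aa in strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
    g <- residue_template(aa)
    expect_equal(sum(g$nodes$backbone_role == "CA"), 1L, info = aa)
    expect_true(all(g$nodes$total_hydrogens >= 0), info = aa)
    expect_true(all(g$nodes$formal_charge == 0), info = aa)
  }
})

test_that("peptide condensation follows the worked examples and the poly-G law", {
  g2 <- seq_to_graph("GG")
  expect_equal(nrow(g2$nodes), 9L)
  expect_equal(nrow(g2$edges), 8L)
  # internal amide N carries one hydrogen, proline's none
  n_roles <- g2$nodes$backbone_role == "N"
  expect_equal(g2$nodes$total_hydrogens[n_roles], c(2L, 1L))
  gp <- seq_to_graph("GP")
  expect_equal(gp$nodes$total_hydrogens[gp$nodes$backbone_role == "N"],
               c(2L, 0L))

  for (L in c(1L, 2L, 5L, 10L)) {
    g <- seq_to_graph(strrep("G", L))
    expect_equal(nrow(g$nodes), 4L * L + 1L)
    expect_equal(nrow(g$edges), 4L * L)
  }

  expect_error(seq_to_graph("GX"), "invalid residue")
  expect_error(seq_to_graph(""), "non-empty")
})

test_that("degree fields equal incidence counts; no self-loops or duplicates", {
  for (s in c("ACDEF", "WWP", "CASSLGQAYEQYF")) {
    g <- seq_to_graph(s)
    deg <- tabulate(c(g$edges$from, g$edges$to), nbins = nrow(g$nodes))
    expect_equal(g$nodes$degree, as.integer(deg))
    expect_true(all(g$edges$from != g$edges$to))
    key <- paste(pmin(g$edges$from, g$edges$to),
                 pmax(g$edges$from, g$edges$to))
    expect_equal(anyDuplicated(key), 0L)
  }
})

test_that("graph_census reports counts and the ring law", {
  cg <- graph_census(seq_to_graph("G"))
  expect_equal(cg[c("nodes", "edges", "rings")],
               list(nodes = 5L, edges = 4L, rings = 0L))
  expect_equal(graph_census(seq_to_graph("F"))$rings, 1L)
  expect_equal(graph_census(seq_to_graph("W"))$rings, 2L)  # fused indole
  for (s in random_peptides(20, max_len = 12, seed = 42)) {
    cen <- graph_census(seq_to_graph(s))
    expect_equal(cen$rings, cen$edges - cen$nodes + 1L)
    expect_gte(cen$rings, 0L)
  }
})

test_that("chain concatenation obeys the condensation length law", {
  for (pair in list(c("GG", "AC"), c("WY", "PQR"), c("A", "A"))) {
    s1 <- pair[1]; s2 <- pair[2]
    joint <- seq_to_graph(paste0(s1, s2))
    a <- seq_to_graph(s1); b <- seq_to_graph(s2)
    expect_equal(nrow(joint$nodes), nrow(a$nodes) + nrow(b$nodes) - 1L)
    expect_equal(nrow(joint$edges), nrow(a$edges) + nrow(b$edges))
  }
})

test_that("graph construction is a pure function with stable node order", {
  g1 <- seq_to_graph("CASSLGF")
  g2 <- seq_to_graph("CASSLGF")
  expect_identical(g1, g2)
  expect_equal(g1$nodes$residue_index, sort(g1$nodes$residue_index))
})

test_that("graphs are connected single chains", {
  for (s in c("G", "AW", random_peptides(5, max_len = 10, seed = 7))) {
    g <- seq_to_graph(s)
    n <- nrow(g$nodes)
    reached <- rep(FALSE, n)
    reached[1] <- TRUE
    frontier <- 1L
    adj_from <- c(g$edges$from, g$edges$to)
    adj_to <- c(g$edges$to, g$edges$from)
    while (length(frontier)) {
      nxt <- unique(adj_to[adj_from %in% frontier])
      frontier <- nxt[!reached[nxt]]
      reached[frontier] <- TRUE
    }
    expect_true(all(reached), info = s)
  }
})

test_that("node and edge tables export losslessly", {
  g <- seq_to_graph("ACD")
  np <- tempfile(fileext = ".tsv"); ep <- tempfile(fileext = ".tsv")
  write_graph_tsv(g, np, ep)
  nodes <- read.delim(np)
  edges <- read.delim(ep)
  expect_equal(nrow(nodes), nrow(g$nodes))
  expect_equal(edges$from, g$edges$from)
  expect_equal(nodes$backbone_role, g$nodes$backbone_role)
})

test_that("construction agrees with an independent cheminformatics toolkit", {
  skip_if_not(rdkit_available(), "python rdkit oracle not available")
  seqs <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
            random_peptides(25, max_len = 15, seed = 99))
  oracle <- rdkit_census(seqs)
  for (i in seq_along(seqs)) {
    g <- seq_to_graph(seqs[i])
    expect_equal(nrow(g$nodes), oracle$nodes[i], info = seqs[i])
    expect_equal(nrow(g$edges), oracle$edges[i], info = seqs[i])
    expect_equal(sum(g$nodes$aromatic), oracle$aromatic[i], info = seqs[i])
    expect_equal(sort(g$nodes$element), sort(oracle$elements[[i]]),
                 info = seqs[i])
    expect_equal(sort(g$nodes$degree), sort(oracle$degrees[[i]]),
                 info = seqs[i])
  }
})
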