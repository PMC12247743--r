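# Heavy-atom residue templates for the 20 standard amino acids (free,
# neutral form: N-terminal amine, C-terminal carboxylic acid).  Atom order is
# the PDB convention (N, CA, C, O, side chain, OXT last); the order is frozen
# so that assembled peptide graphs are bit-reproducible.  Hydrogens are not
# atoms; they are bookkept in `hs`.  Verified against an independent
# cheminformatics toolkit in the test suite.
#
# Each template: atoms data.frame(name, element, aromatic, charge, hyb, hs,
# role) and bonds data.frame(a1, a2, type, conjugated, ring) referencing atom
# names.  Bond stereo is uniformly "none" for sequence-derived peptides.

.aa_templates <- list(
  A = list(
    atoms = data.frame(
      name     = c("N", "CA", "C", "O", "CB", "OXT"),
      element  = c(7L, 6L, 6L, 8L, 6L, 8L),
      aromatic = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
      charge   = c(0L, 0L, 0L, 0L, 0L, 0L),
      hyb      = c("sp3", "sp3", "sp2", "sp2", "sp3", "sp2"),
      hs       = c(2L, 1L, 0L, 0L, 3L, 1L),
      role     = c("N", "CA", "C", "O", "sidechain", "terminal_O")),
    bonds = data.frame(
      a1 = c("N", "CA", "C", "CA", "C"),
      a2 = c("CA", "C", "O", "CB", "OXT"),
      type = c("single", "single", "double", "single", "single"),
      conjugated = c(FALSE, FALSE, TRUE, FALSE, TRUE),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE))
  ),
  C = list(
    atoms = data.frame(
      name     = c("N", "CA", "C", "O", "CB", "SG", "OXT"),
      element  = c(7L, 6L, 6L, 8L, 6L, 16L, 8L),
      aromatic = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
      charge   = c(0L, 0L, 0L, 0L, 0L, 0L, 0L),
      hyb      = c("sp3", "sp3", "sp2", "sp2", "sp3", "sp3", "sp2"),
      hs       = c(2L, 1L, 0L, 0L, 2L, 1L, 1L),
      role     = c("N", "CA", "C", "O", "sidechain", "sidechain", "terminal_O")),
    bonds = data.frame(
      a1 = c("N", "CA", "C", "CA", "CB", "C"),
      a2 = c("CA", "C", "O", "CB", "SG", "OXT"),
      type = c("single", "single", "double", "single", "single", "single"),
      conjugated = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
  ),
  D = list(
    atoms = data.frame(
      name     = c("N", "CA", "C", "O", "CB", "CG", "OD1", "OD2", "OXT"),
      element  = c(7L, 6L, 6L, 8L, 6L, 6L, 8L, 8L, 8L),
      aromatic = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
      charge   = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
      hyb      = c("sp3", "sp3", "sp2", "sp2", "sp3", "sp2", "sp2", "sp2", "sp2"),
      hs       = c(2L, 1L, 0L, 0L, 2L, 0L, 0L, 1L, 1L),
      role     = c("N", "CA", "C", "O", "sidechain", "sidechain", "sidechain", "sidechain", "terminal_O")),
    bonds = data.frame(
      a1 = c("N", "CA", "C", "CA", "CB", "CG", "CG", "C"),
      a2 = c("CA", "C", "O", "CB", "CG", "OD1", "OD2", "OXT"),
      type = c("single", "single", "double", "single", "single", "double", "single", "single"),
      conjugated = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
  ),
  E = list(
    atoms = data.frame(
      name     = c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "OE2", "OXT"),
      element  = c(7L, 6L, 6L, 8L, 6L, 6L, 6L, 8L, 8L, 8L),
      aromatic = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
      charge   = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
      hyb      = c("sp3", "sp3", "sp2", "sp2", "sp3", "sp3", "sp2", "sp2", "sp2", "sp2"),
      hs       = c(2L, 1L, 0L, 0L, 2L, 2L, 0L, 0L, 1L, 1L),
      role     = c("N", "CA", "C", "O", "sidechain", "sidechain", "sidechain", "sidechain", "sidechain", "terminal_O")),
    bonds = data.frame(
      a1 = c("N", "CA", "C", "CA", "CB", "CG", "CD", "CD", "C"),
      a2 = c("CA", "C", "O", "CB", "CG", "CD", "OE1", "OE2", "OXT"),
      type = c("single", "single", "double", "single", "single", "single", "double", "single", "single"),
      conjugated = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
  ),
  F = list(
    atoms = data.frame(
      name     = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OXT"),
      element  = c(7L, 6L, 6L, 8L, 6L, 6L, 6L, 6L, 6L, 6L, 6L, 8L),
      aromatic = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
      charge   = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
      hyb      = c("sp3", "sp3", "sp2", "sp2", "sp3", "sp2", "sp2", "sp2", "sp2", "sp2", "sp2", "sp2"),
      hs       = c(2L, 1L, 0L, 0L, 2L, 0L, 1L, 1L, 1L, 1L, 1L, 1L),
      role     = c("N", "CA", "C", "O", "sidechain", "sidechain", "sidechain", "sidechain", "sidechain", "sidechain", "sidechain", "terminal_O")),
    bonds = data.frame(
      a1 = c("N", "CA", "C", "CA", "CB", "CG", "CD1", "CE1", "CZ", "CE2", "CD2", "C"),
      a2 = c("CA", "C", "O", "CB", "CG", "CD1", "CE1", "CZ", "CE2", "CD2", "CG", "OXT"),
      type = c("single", "single", "double", "single", "single", "aromatic", "aromatic", "aromatic", "aromatic", "aromatic", "aromatic", "single"),
      conjugated = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  ),
  G = list(
    atoms = data.frame(
      name     = c("N", "CA", "C", "O", "OXT"),
      element  = c(7L, 6L, 6L, 8L, 8L),
      aromatic = c(FALSE, FALSE, FALSE, FALSE, FALSE),
      charge   = c(0L, 0L, 0L, 0L, 0L),
      hyb      = c("sp3", "sp3", "sp2", "sp2", "sp2"),
      hs       = c(2L, 2L, 0L, 0L, 1L),
      role     = c("N", "CA", "C", "O", "terminal_O")),
    bonds = data.frame(
      a1 = c("N", "CA", "C", "C"),
      a2 = c("CA", "C", "O", "OXT"),
      type = c("single", "single", "double", "single"),
      conjugated = c(FALSE, FALSE, TRUE, TRUE),
      ring = c(FALSE, FALSE, FALSE, FALSE))
  ),
  H = list(
    atoms = data.frame(
      name     = c("N", "CA", "C", "O", "CB", "CG", "ND1", "CD2", "CE1", "NE2", "OXT"),
      element  = c(7L, 6L, 6L, 8L, 6L, 6L, 7L, 6L, 6L, 7L, 8L),
      aromatic = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
      charge   = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
      hyb      = c("sp3", "sp3", "sp2", "sp2", "sp3", "sp2", "sp2", "sp2", "sp2", "sp2", "sp2"),
      hs       = c(2L, 1L, 0L, 0L, 2L, 0L, 0L, 1L, 1L, 1L, 1L),
      role     = c("N", "CA", "C", "O", "sidechain", "sidechain", "sidechain", "sidechain", "sidechain", "sidechain", "terminal_O")),
    bonds = data.frame(
      a1 = c("N", "CA", "C", "CA", "CB", "CG", "ND1", "CE1", "NE2", "CD2", "C"),
      a2 = c("CA", "C", "O", "CB", "CG", "ND1", "CE1", "NE2", "CD2", "CG", "OXT"),
      type = c("single", "single", "double", "single", "single", "aromatic", "aromatic", "aromatic", "aromatic", "aromatic", "single"),
      conjugated = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  ),
  I = list(
    atoms = data.frame(
      name     = c("N", "CA", "C", "O", "CB", "CG1", "CG2", "CD1", "OXT"),
      element  = c(7L, 6L, 6L, 8L, 6L, 6L, 6L, 6L, 8L),
      aromatic = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
      charge   = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
      hyb      = c("sp3", "sp3", "sp2", "sp2", "sp3", "sp3", "sp3", "sp3", "sp2"),
      hs       = c(2L, 1L, 0L, 0L, 1L, 3L, 2L, 3L, 1L),
      role     = c("N", "CA", "C", "O", "sidechain", "sidechain", "sidechain", "sidechain", "terminal_O")),
    bonds = data.frame(
      a1 = c("N", "CA", "C", "CA", "CB", "CB", "CG2", "C"),
      a2 = c("CA", "C", "O", "CB", "CG1", "CG2", "CD1", "OXT"),
      type = c("single", "single", "double", "single", "single", "single", "single", "single"),
      conjugated = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
  ),
  K = list(
    atoms = data.frame(
      name     = c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ", "OXT"),
      element  = c(7L, 6L, 6L, 8L, 6L, 6L, 6L, 6L, 7L, 8L),
      aromatic = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
      charge   = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
      hyb      = c("sp3", "sp3", "sp2", "sp2", "sp3", "sp3", "sp3", "sp3", "sp3", "sp2"),
      hs       = c(2L, 1L, 0L, 0L, 2L, 2L, 2L, 2L, 2L, 1L),
      role     = c("N", "CA", "C", "O", "sidechain", "sidechain", "sidechain", "sidechain", "sidechain", "terminal_O")),
    bonds = data.frame(
      a1 = c("N", "CA", "C", "CA", "CB", "CG", "CD", "CE", "C"),
      a2 = c("CA", "C", "O", "CB", "CG", "CD", "CE", "NZ", "OXT"),
      type = c("single", "single", "double", "single", "single", "single", "single", "single", "single"),
      conjugated = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
  ),
  L = list(
    atoms = data.frame(
      name     = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "OXT"),
      element  = c(7L, 6L, 6L, 8L, 6L, 6L, 6L, 6L, 8L),
      aromatic = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
      charge   = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
      hyb      = c("sp3", "sp3", "sp2", "sp2", "sp3", "sp3", "sp3", "sp3", "sp2"),
      hs       = c(2L, 1L, 0L, 0L, 2L, 1L, 3L, 3L, 1L),
      role     = c("N", "CA", "C", "O", "sidechain", "sidechain", "sidechain", "sidechain", "terminal_O")),
    bonds = data.frame(
      a1 = c("N", "CA", "C", "CA", "CB", "CG", "CG", "C"),
      a2 = c("CA", "C", "O", "CB", "CG", "CD1", "CD2", "OXT"),
      type = c("single", "single", "double", "single", "single", "single", "single", "single"),
      conjugated = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
  ),
  M = list(
    atoms = data.frame(
      name     = c("N", "CA", "C", "O", "CB", "CG", "SD", "CE", "OXT"),
      element  = c(7L, 6L, 6L, 8L, 6L, 6L, 16L, 6L, 8L),
      aromatic = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
      charge   = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
      hyb      = c("sp3", "sp3", "sp2", "sp2", "sp3", "sp3", "sp3", "sp3", "sp2"),
      hs       = c(2L, 1L, 0L, 0L, 2L, 2L, 0L, 3L, 1L),
      role     = c("N", "CA", "C", "O", "sidechain", "sidechain", "sidechain", "sidechain", "terminal_O")),
    bonds = data.frame(
      a1 = c("N", "CA", "C", "CA", "CB", "CG", "SD", "C"),
      a2 = c("CA", "C", "O", "CB", "CG", "SD", "CE", "OXT"),
      type = c("single", "single", "double", "single", "single", "single", "single", "single"),
      conjugated = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
  ),
  N = list(
    atoms = data.frame(
      name     = c("N", "CA", "C", "O", "CB", "CG", "OD1", "ND2", "OXT"),
      element  = c(7L, 6L, 6L, 8L, 6L, 6L, 8L, 7L, 8L),
      aromatic = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
      charge   = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
      hyb      = c("sp3", "sp3", "sp2", "sp2", "sp3", "sp2", "sp2", "sp2", "sp2"),
      hs       = c(2L, 1L, 0L, 0L, 2L, 0L, 0L, 2L, 1L),
      role     = c("N", "CA", "C", "O", "sidechain", "sidechain", "sidechain", "sidechain", "terminal_O")),
    bonds = data.frame(
      a1 = c("N", "CA", "C", "CA", "CB", "CG", "CG", "C"),
      a2 = c("CA", "C", "O", "CB", "CG", "OD1", "ND2", "OXT"),
      type = c("single", "single", "double", "single", "single", "double", "single", "single"),
      conjugated = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
  ),
  P = list(
    atoms = data.frame(
      name     = c("N", "CA", "C", "O", "CB", "CG", "CD", "OXT"),
      element  = c(7L, 6L, 6L, 8L, 6L, 6L, 6L, 8L),
      aromatic = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
      charge   = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
      hyb      = c("sp3", "sp3", "sp2", "sp2", "sp3", "sp3", "sp3", "sp2"),
      hs       = c(1L, 1L, 0L, 0L, 2L, 2L, 2L, 1L),
      role     = c("N", "CA", "C", "O", "sidechain", "sidechain", "sidechain", "terminal_O")),
    bonds = data.frame(
      a1 = c("N", "CA", "C", "CA", "CB", "CG", "CD", "C"),
      a2 = c("CA", "C", "O", "CB", "CG", "CD", "N", "OXT"),
      type = c("single", "single", "double", "single", "single", "single", "single", "single"),
      conjugated = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE),
      ring = c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE))
  ),
  Q = list(
    atoms = data.frame(
      name     = c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "NE2", "OXT"),
      element  = c(7L, 6L, 6L, 8L, 6L, 6L, 6L, 8L, 7L, 8L),
      aromatic = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
      charge   = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
      hyb      = c("sp3", "sp3", "sp2", "sp2", "sp3", "sp3", "sp2", "sp2", "sp2", "sp2"),
      hs       = c(2L, 1L, 0L, 0L, 2L, 2L, 0L, 0L, 2L, 1L),
      role     = c("N", "CA", "C", "O", "sidechain", "sidechain", "sidechain", "sidechain", "sidechain", "terminal_O")),
    bonds = data.frame(
      a1 = c("N", "CA", "C", "CA", "CB", "CG", "CD", "CD", "C"),
      a2 = c("CA", "C", "O", "CB", "CG", "CD", "OE1", "NE2", "OXT"),
      type = c("single", "single", "double", "single", "single", "single", "double", "single", "single"),
      conjugated = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
  ),
  R = list(
    atoms = data.frame(
      name     = c("N", "CA", "C", "O", "CB", "CG", "CD", "NE", "CZ", "NH1", "NH2", "OXT"),
      element  = c(7L, 6L, 6L, 8L, 6L, 6L, 6L, 7L, 6L, 7L, 7L, 8L),
      aromatic = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
      charge   = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
      hyb      = c("sp3", "sp3", "sp2", "sp2", "sp3", "sp3", "sp3", "sp2", "sp2", "sp2", "sp2", "sp2"),
      hs       = c(2L, 1L, 0L, 0L, 2L, 2L, 2L, 1L, 0L, 1L, 2L, 1L),
      role     = c("N", "CA", "C", "O", "sidechain", "sidechain", "sidechain", "sidechain", "sidechain", "sidechain", "sidechain", "terminal_O")),
    bonds = data.frame(
      a1 = c("N", "CA", "C", "CA", "CB", "CG", "CD", "NE", "CZ", "CZ", "C"),
      a2 = c("CA", "C", "O", "CB", "CG", "CD", "NE", "CZ", "NH1", "NH2", "OXT"),
      type = c("single", "single", "double", "single", "single", "single", "single", "single", "double", "single", "single"),
      conjugated = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
  ),
  S = list(
    atoms = data.frame(
      name     = c("N", "CA", "C", "O", "CB", "OG", "OXT"),
      element  = c(7L, 6L, 6L, 8L, 6L, 8L, 8L),
      aromatic = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
      charge   = c(0L, 0L, 0L, 0L, 0L, 0L, 0L),
      hyb      = c("sp3", "sp3", "sp2", "sp2", "sp3", "sp3", "sp2"),
      hs       = c(2L, 1L, 0L, 0L, 2L, 1L, 1L),
      role     = c("N", "CA", "C", "O", "sidechain", "sidechain", "terminal_O")),
    bonds = data.frame(
      a1 = c("N", "CA", "C", "CA", "CB", "C"),
      a2 = c("CA", "C", "O", "CB", "OG", "OXT"),
      type = c("single", "single", "double", "single", "single", "single"),
      conjugated = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
  ),
  T = list(
    atoms = data.frame(
      name     = c("N", "CA", "C", "O", "CB", "OG1", "CG2", "OXT"),
      element  = c(7L, 6L, 6L, 8L, 6L, 8L, 6L, 8L),
      aromatic = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
      charge   = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
      hyb      = c("sp3", "sp3", "sp2", "sp2", "sp3", "sp3", "sp3", "sp2"),
      hs       = c(2L, 1L, 0L, 0L, 1L, 1L, 3L, 1L),
      role     = c("N", "CA", "C", "O", "sidechain", "sidechain", "sidechain", "terminal_O")),
    bonds = data.frame(
      a1 = c("N", "CA", "C", "CA", "CB", "CB", "C"),
      a2 = c("CA", "C", "O", "CB", "OG1", "CG2", "OXT"),
      type = c("single", "single", "double", "single", "single", "single", "single"),
      conjugated = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
  ),
  V = list(
    atoms = data.frame(
      name     = c("N", "CA", "C", "O", "CB", "CG1", "CG2", "OXT"),
      element  = c(7L, 6L, 6L, 8L, 6L, 6L, 6L, 8L),
      aromatic = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
      charge   = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
      hyb      = c("sp3", "sp3", "sp2", "sp2", "sp3", "sp3", "sp3", "sp2"),
      hs       = c(2L, 1L, 0L, 0L, 1L, 3L, 3L, 1L),
      role     = c("N", "CA", "C", "O", "sidechain", "sidechain", "sidechain", "terminal_O")),
    bonds = data.frame(
      a1 = c("N", "CA", "C", "CA", "CB", "CB", "C"),
      a2 = c("CA", "C", "O", "CB", "CG1", "CG2", "OXT"),
      type = c("single", "single", "double", "single", "single", "single", "single"),
      conjugated = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
  ),
  W = list(
    atoms = data.frame(
      name     = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2", "OXT"),
      element  = c(7L, 6L, 6L, 8L, 6L, 6L, 6L, 6L, 7L, 6L, 6L, 6L, 6L, 6L, 8L),
      aromatic = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
      charge   = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
      hyb      = c("sp3", "sp3", "sp2", "sp2", "sp3", "sp2", "sp2", "sp2", "sp2", "sp2", "sp2", "sp2", "sp2", "sp2", "sp2"),
      hs       = c(2L, 1L, 0L, 0L, 2L, 0L, 1L, 0L, 1L, 0L, 1L, 1L, 1L, 1L, 1L),
      role     = c("N", "CA", "C", "O", "sidechain", "sidechain", "sidechain", "sidechain", "sidechain", "sidechain", "sidechain", "sidechain", "sidechain", "sidechain", "terminal_O")),
    bonds = data.frame(
      a1 = c("N", "CA", "C", "CA", "CB", "CG", "CG", "CD1", "CD2", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "C"),
      a2 = c("CA", "C", "O", "CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CE2", "CZ2", "CZ3", "CH2", "CH2", "OXT"),
      type = c("single", "single", "double", "single", "single", "aromatic", "aromatic", "aromatic", "aromatic", "aromatic", "aromatic", "aromatic", "aromatic", "aromatic", "aromatic", "single"),
      conjugated = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  ),
  Y = list(
    atoms = data.frame(
      name     = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH", "OXT"),
      element  = c(7L, 6L, 6L, 8L, 6L, 6L, 6L, 6L, 6L, 6L, 6L, 8L, 8L),
      aromatic = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
      charge   = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
      hyb      = c("sp3", "sp3", "sp2", "sp2", "sp3", "sp2", "sp2", "sp2", "sp2", "sp2", "sp2", "sp2", "sp2"),
      hs       = c(2L, 1L, 0L, 0L, 2L, 0L, 1L, 1L, 1L, 1L, 0L, 1L, 1L),
      role     = c("N", "CA", "C", "O", "sidechain", "sidechain", "sidechain", "sidechain", "sidechain", "sidechain", "sidechain", "sidechain", "terminal_O")),
    bonds = data.frame(
      a1 = c("N", "CA", "C", "CA", "CB", "CG", "CD1", "CE1", "CZ", "CE2", "CD2", "CZ", "C"),
      a2 = c("CA", "C", "O", "CB", "CG", "CD1", "CE1", "CZ", "CE2", "CD2", "CG", "OH", "OXT"),
      type = c("single", "single", "double", "single", "single", "aromatic", "aromatic", "aromatic", "aromatic", "aromatic", "aromatic", "single", "single"),
      conjugated = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  )
)
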