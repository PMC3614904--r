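# Generated amino-acid ideal-geometry templates (do not edit by hand;
# regenerated from standard residue definitions). Dihedral conventions:
# each sidechain atom X is placed from reference atoms (a, b, c) with
# bond |X-c|, angle b-c-X and dihedral a-b-c-X; dihedral is either a
# chi variable (dih_chi > 0, plus dih_off) or a fixed constant.
.aa_template_raw <- list(
  ALA = list(
    aa1 = "A",
    sc = list(
      list(name = "CB", el = "C", refs = c("C", "N", "CA"), bond = 1.529, angle = 109.46, dih_chi = 0L, dih_off = 0.00, dih_const = -120.00)
    ),
    chi_defs = list(),
    extra_bonds = list(),
    flip_chi = 0L,
    flip_pairs = list()
  ),
  ARG = list(
    aa1 = "R",
    sc = list(
      list(name = "CB", el = "C", refs = c("C", "N", "CA"), bond = 1.536, angle = 111.55, dih_chi = 0L, dih_off = 0.00, dih_const = -123.56),
      list(name = "CG", el = "C", refs = c("N", "CA", "CB"), bond = 1.537, angle = 114.54, dih_chi = 1L, dih_off = 0.00, dih_const = 0.00),
      list(name = "CD", el = "C", refs = c("CA", "CB", "CG"), bond = 1.527, angle = 112.42, dih_chi = 2L, dih_off = 0.00, dih_const = 0.00),
      list(name = "NE", el = "N", refs = c("CB", "CG", "CD"), bond = 1.444, angle = 111.02, dih_chi = 3L, dih_off = 0.00, dih_const = 0.00),
      list(name = "CZ", el = "C", refs = c("CG", "CD", "NE"), bond = 1.406, angle = 123.00, dih_chi = 4L, dih_off = 0.00, dih_const = 0.00),
      list(name = "NH1", el = "N", refs = c("CD", "NE", "CZ"), bond = 1.391, angle = 121.00, dih_chi = 0L, dih_off = 0.00, dih_const = 179.99),
      list(name = "NH2", el = "N", refs = c("CD", "NE", "CZ"), bond = 1.391, angle = 119.81, dih_chi = 0L, dih_off = 0.00, dih_const = -0.01)
    ),
    chi_defs = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"), c("CB", "CG", "CD", "NE"), c("CG", "CD", "NE", "CZ")),
    extra_bonds = list(),
    flip_chi = 0L,
    flip_pairs = list()
  ),
  ASN = list(
    aa1 = "N",
    sc = list(
      list(name = "CB", el = "C", refs = c("C", "N", "CA"), bond = 1.531, angle = 109.45, dih_chi = 0L, dih_off = 0.00, dih_const = -120.00),
      list(name = "CG", el = "C", refs = c("N", "CA", "CB"), bond = 1.507, angle = 109.48, dih_chi = 1L, dih_off = 0.00, dih_const = 0.00),
      list(name = "OD1", el = "O", refs = c("CA", "CB", "CG"), bond = 1.213, angle = 119.97, dih_chi = 2L, dih_off = 0.00, dih_const = 0.00),
      list(name = "ND2", el = "N", refs = c("CA", "CB", "CG"), bond = 1.348, angle = 120.01, dih_chi = 2L, dih_off = -179.93, dih_const = 0.00)
    ),
    chi_defs = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
    extra_bonds = list(),
    flip_chi = 2L,
    flip_pairs = list(c("OD1", "ND2"))
  ),
  ASP = list(
    aa1 = "D",
    sc = list(
      list(name = "CB", el = "C", refs = c("C", "N", "CA"), bond = 1.530, angle = 109.48, dih_chi = 0L, dih_off = 0.00, dih_const = -120.01),
      list(name = "CG", el = "C", refs = c("N", "CA", "CB"), bond = 1.508, angle = 109.46, dih_chi = 1L, dih_off = 0.00, dih_const = 0.00),
      list(name = "OD1", el = "O", refs = c("CA", "CB", "CG"), bond = 1.208, angle = 119.96, dih_chi = 2L, dih_off = 0.00, dih_const = 0.00),
      list(name = "OD2", el = "O", refs = c("CA", "CB", "CG"), bond = 1.341, angle = 120.00, dih_chi = 2L, dih_off = -179.94, dih_const = 0.00)
    ),
    chi_defs = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
    extra_bonds = list(),
    flip_chi = 0L,
    flip_pairs = list()
  ),
  CYS = list(
    aa1 = "C",
    sc = list(
      list(name = "CB", el = "C", refs = c("C", "N", "CA"), bond = 1.528, angle = 109.50, dih_chi = 0L, dih_off = 0.00, dih_const = -120.01),
      list(name = "SG", el = "S", refs = c("N", "CA", "CB"), bond = 1.814, angle = 109.50, dih_chi = 1L, dih_off = 0.00, dih_const = 0.00)
    ),
    chi_defs = list(c("N", "CA", "CB", "SG")),
    extra_bonds = list(),
    flip_chi = 0L,
    flip_pairs = list()
  ),
  GLN = list(
    aa1 = "Q",
    sc = list(
      list(name = "CB", el = "C", refs = c("C", "N", "CA"), bond = 1.529, angle = 109.46, dih_chi = 0L, dih_off = 0.00, dih_const = -120.07),
      list(name = "CG", el = "C", refs = c("N", "CA", "CB"), bond = 1.528, angle = 109.53, dih_chi = 1L, dih_off = 0.00, dih_const = 0.00),
      list(name = "CD", el = "C", refs = c("CA", "CB", "CG"), bond = 1.507, angle = 109.54, dih_chi = 2L, dih_off = 0.00, dih_const = 0.00),
      list(name = "OE1", el = "O", refs = c("CB", "CG", "CD"), bond = 1.212, angle = 119.94, dih_chi = 3L, dih_off = 0.00, dih_const = 0.00),
      list(name = "NE2", el = "N", refs = c("CB", "CG", "CD"), bond = 1.347, angle = 120.09, dih_chi = 3L, dih_off = -179.96, dih_const = 0.00)
    ),
    chi_defs = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"), c("CB", "CG", "CD", "OE1")),
    extra_bonds = list(),
    flip_chi = 3L,
    flip_pairs = list(c("OE1", "NE2"))
  ),
  GLU = list(
    aa1 = "E",
    sc = list(
      list(name = "CB", el = "C", refs = c("C", "N", "CA"), bond = 1.530, angle = 109.48, dih_chi = 0L, dih_off = 0.00, dih_const = -119.96),
      list(name = "CG", el = "C", refs = c("N", "CA", "CB"), bond = 1.531, angle = 109.40, dih_chi = 1L, dih_off = 0.00, dih_const = 0.00),
      list(name = "CD", el = "C", refs = c("CA", "CB", "CG"), bond = 1.508, angle = 109.43, dih_chi = 2L, dih_off = 0.00, dih_const = 0.00),
      list(name = "OE1", el = "O", refs = c("CB", "CG", "CD"), bond = 1.208, angle = 120.00, dih_chi = 3L, dih_off = 0.00, dih_const = 0.00),
      list(name = "OE2", el = "O", refs = c("CB", "CG", "CD"), bond = 1.343, angle = 120.00, dih_chi = 3L, dih_off = -179.94, dih_const = 0.00)
    ),
    chi_defs = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"), c("CB", "CG", "CD", "OE1")),
    extra_bonds = list(),
    flip_chi = 0L,
    flip_pairs = list()
  ),
  GLY = list(
    aa1 = "G",
    sc = list(

    ),
    chi_defs = list(),
    extra_bonds = list(),
    flip_chi = 0L,
    flip_pairs = list()
  ),
  HIS = list(
    aa1 = "H",
    sc = list(
      list(name = "CB", el = "C", refs = c("C", "N", "CA"), bond = 1.534, angle = 111.13, dih_chi = 0L, dih_off = 0.00, dih_const = -122.78),
      list(name = "CG", el = "C", refs = c("N", "CA", "CB"), bond = 1.510, angle = 112.98, dih_chi = 1L, dih_off = 0.00, dih_const = 0.00),
      list(name = "ND1", el = "N", refs = c("CA", "CB", "CG"), bond = 1.351, angle = 120.33, dih_chi = 2L, dih_off = 0.00, dih_const = 0.00),
      list(name = "CD2", el = "C", refs = c("CA", "CB", "CG"), bond = 1.338, angle = 129.93, dih_chi = 2L, dih_off = 179.85, dih_const = 0.00),
      list(name = "CE1", el = "C", refs = c("CB", "CG", "ND1"), bond = 1.337, angle = 107.86, dih_chi = 0L, dih_off = 0.00, dih_const = 179.90),
      list(name = "NE2", el = "N", refs = c("CG", "ND1", "CE1"), bond = 1.337, angle = 107.62, dih_chi = 0L, dih_off = 0.00, dih_const = -0.04)
    ),
    chi_defs = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "ND1")),
    extra_bonds = list(c("NE2", "CD2")),
    flip_chi = 2L,
    flip_pairs = list(c("ND1", "CD2"), c("CE1", "NE2"))
  ),
  ILE = list(
    aa1 = "I",
    sc = list(
      list(name = "CB", el = "C", refs = c("C", "N", "CA"), bond = 1.529, angle = 109.43, dih_chi = 0L, dih_off = 0.00, dih_const = -120.07),
      list(name = "CG1", el = "C", refs = c("N", "CA", "CB"), bond = 1.529, angle = 109.55, dih_chi = 1L, dih_off = 0.00, dih_const = 0.00),
      list(name = "CG2", el = "C", refs = c("N", "CA", "CB"), bond = 1.530, angle = 109.46, dih_chi = 1L, dih_off = -119.97, dih_const = 0.00),
      list(name = "CD1", el = "C", refs = c("CA", "CB", "CG1"), bond = 1.529, angle = 109.55, dih_chi = 2L, dih_off = 0.00, dih_const = 0.00)
    ),
    chi_defs = list(c("N", "CA", "CB", "CG1"), c("CA", "CB", "CG1", "CD1")),
    extra_bonds = list(),
    flip_chi = 0L,
    flip_pairs = list()
  ),
  LEU = list(
    aa1 = "L",
    sc = list(
      list(name = "CB", el = "C", refs = c("C", "N", "CA"), bond = 1.529, angle = 109.42, dih_chi = 0L, dih_off = 0.00, dih_const = -119.97),
      list(name = "CG", el = "C", refs = c("N", "CA", "CB"), bond = 1.530, angle = 109.49, dih_chi = 1L, dih_off = 0.00, dih_const = 0.00),
      list(name = "CD1", el = "C", refs = c("CA", "CB", "CG"), bond = 1.530, angle = 109.50, dih_chi = 2L, dih_off = 0.00, dih_const = 0.00),
      list(name = "CD2", el = "C", refs = c("CA", "CB", "CG"), bond = 1.529, angle = 109.50, dih_chi = 2L, dih_off = 120.09, dih_const = 0.00)
    ),
    chi_defs = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
    extra_bonds = list(),
    flip_chi = 0L,
    flip_pairs = list()
  ),
  LYS = list(
    aa1 = "K",
    sc = list(
      list(name = "CB", el = "C", refs = c("C", "N", "CA"), bond = 1.530, angle = 109.45, dih_chi = 0L, dih_off = 0.00, dih_const = -119.97),
      list(name = "CG", el = "C", refs = c("N", "CA", "CB"), bond = 1.531, angle = 109.42, dih_chi = 1L, dih_off = 0.00, dih_const = 0.00),
      list(name = "CD", el = "C", refs = c("CA", "CB", "CG"), bond = 1.531, angle = 109.44, dih_chi = 2L, dih_off = 0.00, dih_const = 0.00),
      list(name = "CE", el = "C", refs = c("CB", "CG", "CD"), bond = 1.529, angle = 109.46, dih_chi = 3L, dih_off = 0.00, dih_const = 0.00),
      list(name = "NZ", el = "N", refs = c("CG", "CD", "CE"), bond = 1.469, angle = 109.50, dih_chi = 4L, dih_off = 0.00, dih_const = 0.00)
    ),
    chi_defs = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"), c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ")),
    extra_bonds = list(),
    flip_chi = 0L,
    flip_pairs = list()
  ),
  MET = list(
    aa1 = "M",
    sc = list(
      list(name = "CB", el = "C", refs = c("C", "N", "CA"), bond = 1.529, angle = 109.43, dih_chi = 0L, dih_off = 0.00, dih_const = -120.04),
      list(name = "CG", el = "C", refs = c("N", "CA", "CB"), bond = 1.528, angle = 109.54, dih_chi = 1L, dih_off = 0.00, dih_const = 0.00),
      list(name = "SD", el = "S", refs = c("CA", "CB", "CG"), bond = 1.814, angle = 109.51, dih_chi = 2L, dih_off = 0.00, dih_const = 0.00),
      list(name = "CE", el = "C", refs = c("CB", "CG", "SD"), bond = 1.814, angle = 100.03, dih_chi = 3L, dih_off = 0.00, dih_const = 0.00)
    ),
    chi_defs = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "SD"), c("CB", "CG", "SD", "CE")),
    extra_bonds = list(),
    flip_chi = 0L,
    flip_pairs = list()
  ),
  PHE = list(
    aa1 = "F",
    sc = list(
      list(name = "CB", el = "C", refs = c("C", "N", "CA"), bond = 1.529, angle = 109.47, dih_chi = 0L, dih_off = 0.00, dih_const = -120.09),
      list(name = "CG", el = "C", refs = c("N", "CA", "CB"), bond = 1.505, angle = 109.52, dih_chi = 1L, dih_off = 0.00, dih_const = 0.00),
      list(name = "CD1", el = "C", refs = c("CA", "CB", "CG"), bond = 1.382, angle = 120.06, dih_chi = 2L, dih_off = 0.00, dih_const = 0.00),
      list(name = "CD2", el = "C", refs = c("CA", "CB", "CG"), bond = 1.383, angle = 120.00, dih_chi = 2L, dih_off = 179.76, dih_const = 0.00),
      list(name = "CE1", el = "C", refs = c("CB", "CG", "CD1"), bond = 1.382, angle = 120.03, dih_chi = 0L, dih_off = 0.00, dih_const = 179.99),
      list(name = "CE2", el = "C", refs = c("CB", "CG", "CD2"), bond = 1.382, angle = 119.98, dih_chi = 0L, dih_off = 0.00, dih_const = 179.84),
      list(name = "CZ", el = "C", refs = c("CG", "CD1", "CE1"), bond = 1.381, angle = 120.05, dih_chi = 0L, dih_off = 0.00, dih_const = -0.05)
    ),
    chi_defs = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
    extra_bonds = list(c("CZ", "CE2")),
    flip_chi = 0L,
    flip_pairs = list()
  ),
  PRO = list(
    aa1 = "P",
    sc = list(
      list(name = "CB", el = "C", refs = c("C", "N", "CA"), bond = 1.543, angle = 104.72, dih_chi = 0L, dih_off = 0.00, dih_const = -118.84),
      list(name = "CG", el = "C", refs = c("N", "CA", "CB"), bond = 1.543, angle = 105.06, dih_chi = 0L, dih_off = 0.00, dih_const = -23.80),
      list(name = "CD", el = "C", refs = c("CA", "CB", "CG"), bond = 1.544, angle = 105.06, dih_chi = 0L, dih_off = 0.00, dih_const = 0.03)
    ),
    chi_defs = list(),
    extra_bonds = list(c("CD", "N")),
    flip_chi = 0L,
    flip_pairs = list()
  ),
  SER = list(
    aa1 = "S",
    sc = list(
      list(name = "CB", el = "C", refs = c("C", "N", "CA"), bond = 1.529, angle = 109.47, dih_chi = 0L, dih_off = 0.00, dih_const = -120.02),
      list(name = "OG", el = "O", refs = c("N", "CA", "CB"), bond = 1.428, angle = 109.51, dih_chi = 1L, dih_off = 0.00, dih_const = 0.00)
    ),
    chi_defs = list(c("N", "CA", "CB", "OG")),
    extra_bonds = list(),
    flip_chi = 0L,
    flip_pairs = list()
  ),
  THR = list(
    aa1 = "T",
    sc = list(
      list(name = "CB", el = "C", refs = c("C", "N", "CA"), bond = 1.529, angle = 109.41, dih_chi = 0L, dih_off = 0.00, dih_const = -120.00),
      list(name = "OG1", el = "O", refs = c("N", "CA", "CB"), bond = 1.428, angle = 109.51, dih_chi = 1L, dih_off = 0.00, dih_const = 0.00),
      list(name = "CG2", el = "C", refs = c("N", "CA", "CB"), bond = 1.530, angle = 109.53, dih_chi = 1L, dih_off = -120.03, dih_const = 0.00)
    ),
    chi_defs = list(c("N", "CA", "CB", "OG1")),
    extra_bonds = list(),
    flip_chi = 0L,
    flip_pairs = list()
  ),
  TRP = list(
    aa1 = "W",
    sc = list(
      list(name = "CB", el = "C", refs = c("C", "N", "CA"), bond = 1.529, angle = 109.52, dih_chi = 0L, dih_off = 0.00, dih_const = -120.03),
      list(name = "CG", el = "C", refs = c("N", "CA", "CB"), bond = 1.507, angle = 109.44, dih_chi = 1L, dih_off = 0.00, dih_const = 0.00),
      list(name = "CD1", el = "C", refs = c("CA", "CB", "CG"), bond = 1.343, angle = 126.50, dih_chi = 2L, dih_off = 0.00, dih_const = 0.00),
      list(name = "CD2", el = "C", refs = c("CA", "CB", "CG"), bond = 1.464, angle = 126.51, dih_chi = 2L, dih_off = 179.62, dih_const = 0.00),
      list(name = "NE1", el = "N", refs = c("CB", "CG", "CD1"), bond = 1.369, angle = 109.93, dih_chi = 0L, dih_off = 0.00, dih_const = 179.94),
      list(name = "CE2", el = "C", refs = c("CB", "CG", "CD2"), bond = 1.407, angle = 106.08, dih_chi = 0L, dih_off = 0.00, dih_const = 179.96),
      list(name = "CE3", el = "C", refs = c("CB", "CG", "CD2"), bond = 1.396, angle = 134.05, dih_chi = 0L, dih_off = 0.00, dih_const = 0.78),
      list(name = "CZ2", el = "C", refs = c("CG", "CD2", "CE2"), bond = 1.391, angle = 119.35, dih_chi = 0L, dih_off = 0.00, dih_const = -179.83),
      list(name = "CZ3", el = "C", refs = c("CG", "CD2", "CE3"), bond = 1.366, angle = 119.80, dih_chi = 0L, dih_off = 0.00, dih_const = 179.64),
      list(name = "CH2", el = "C", refs = c("CD2", "CE2", "CZ2"), bond = 1.377, angle = 119.81, dih_chi = 0L, dih_off = 0.00, dih_const = 0.22)
    ),
    chi_defs = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
    extra_bonds = list(c("NE1", "CE2"), c("CH2", "CZ3")),
    flip_chi = 0L,
    flip_pairs = list()
  ),
  TYR = list(
    aa1 = "Y",
    sc = list(
      list(name = "CB", el = "C", refs = c("C", "N", "CA"), bond = 1.529, angle = 109.47, dih_chi = 0L, dih_off = 0.00, dih_const = -120.04),
      list(name = "CG", el = "C", refs = c("N", "CA", "CB"), bond = 1.506, angle = 109.50, dih_chi = 1L, dih_off = 0.00, dih_const = 0.00),
      list(name = "CD1", el = "C", refs = c("CA", "CB", "CG"), bond = 1.382, angle = 119.95, dih_chi = 2L, dih_off = 0.00, dih_const = 0.00),
      list(name = "CD2", el = "C", refs = c("CA", "CB", "CG"), bond = 1.383, angle = 119.94, dih_chi = 2L, dih_off = 179.69, dih_const = 0.00),
      list(name = "CE1", el = "C", refs = c("CB", "CG", "CD1"), bond = 1.381, angle = 120.07, dih_chi = 0L, dih_off = 0.00, dih_const = -179.98),
      list(name = "CE2", el = "C", refs = c("CB", "CG", "CD2"), bond = 1.381, angle = 120.02, dih_chi = 0L, dih_off = 0.00, dih_const = 179.77),
      list(name = "CZ", el = "C", refs = c("CG", "CD1", "CE1"), bond = 1.387, angle = 119.98, dih_chi = 0L, dih_off = 0.00, dih_const = -0.10),
      list(name = "OH", el = "O", refs = c("CD1", "CE1", "CZ"), bond = 1.358, angle = 120.13, dih_chi = 0L, dih_off = 0.00, dih_const = -179.97)
    ),
    chi_defs = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
    extra_bonds = list(c("CZ", "CE2")),
    flip_chi = 0L,
    flip_pairs = list()
  ),
  VAL = list(
    aa1 = "V",
    sc = list(
      list(name = "CB", el = "C", refs = c("C", "N", "CA"), bond = 1.529, angle = 109.45, dih_chi = 0L, dih_off = 0.00, dih_const = -120.00),
      list(name = "CG1", el = "C", refs = c("N", "CA", "CB"), bond = 1.530, angle = 109.51, dih_chi = 1L, dih_off = 0.00, dih_const = 0.00),
      list(name = "CG2", el = "C", refs = c("N", "CA", "CB"), bond = 1.529, angle = 109.49, dih_chi = 1L, dih_off = 120.03, dih_const = 0.00)
    ),
    chi_defs = list(c("N", "CA", "CB", "CG1")),
    extra_bonds = list(),
    flip_chi = 0L,
    flip_pairs = list()
  )
)
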