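# Internal-coordinate templates for the 20 standard L-amino acids plus
# ACE/NME caps.  Side chains are described as Z-matrix rows relative to
# previously placed atoms of the same residue; rings carry explicit closure
# bonds.  Geometry follows standard small-molecule/protein values (Engh &
# Huber-style bond lengths and angles, rounded); side-chain torsions default
# to the extended rotamer.

.AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
          Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
          L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
          S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

.zrow <- function(atom, p, ap, dp, b, a, d) {
  data.frame(atom = atom, p = p, ap = ap, dp = dp, b = b, a = a, d = d,
             stringsAsFactors = FALSE)
}

# CB is placed identically for every non-Gly residue; the torsion
# CB-CA-N-C fixes the L-configuration at the alpha carbon.
.CB_TORSION <- -122.5

.cb_row <- function(b = 1.53, a = 110.5) {
  .zrow("CB", "CA", "N", "C", b, a, .CB_TORSION)
}

.SIDECHAIN <- list(
  ALA = .cb_row(1.521),
  ARG = rbind(
    .cb_row(),
    .zrow("CG",  "CB", "CA", "N",  1.52, 114.1, 180),
    .zrow("CD",  "CG", "CB", "CA", 1.52, 111.3, 180),
    .zrow("NE",  "CD", "CG", "CB", 1.46, 112.0, 180),
    .zrow("CZ",  "NE", "CD", "CG", 1.33, 124.2, 180),
    .zrow("NH1", "CZ", "NE", "CD", 1.33, 120.0, 0),
    .zrow("NH2", "CZ", "NE", "CD", 1.33, 120.0, 180)),
  ASN = rbind(
    .cb_row(),
    .zrow("CG",  "CB", "CA", "N",  1.52, 112.6, 180),
    .zrow("OD1", "CG", "CB", "CA", 1.23, 120.8, 0),
    .zrow("ND2", "CG", "CB", "CA", 1.33, 116.4, 180)),
  ASP = rbind(
    .cb_row(),
    .zrow("CG",  "CB", "CA", "N",  1.52, 112.6, 180),
    .zrow("OD1", "CG", "CB", "CA", 1.25, 118.4, 0),
    .zrow("OD2", "CG", "CB", "CA", 1.25, 118.4, 180)),
  CYS = rbind(
    .cb_row(),
    .zrow("SG", "CB", "CA", "N", 1.81, 114.4, 180)),
  GLN = rbind(
    .cb_row(),
    .zrow("CG",  "CB", "CA", "N",  1.52, 114.1, 180),
    .zrow("CD",  "CG", "CB", "CA", 1.52, 112.6, 180),
    .zrow("OE1", "CD", "CG", "CB", 1.23, 120.8, 0),
    .zrow("NE2", "CD", "CG", "CB", 1.33, 116.4, 180)),
  GLU = rbind(
    .cb_row(),
    .zrow("CG",  "CB", "CA", "N",  1.52, 114.1, 180),
    .zrow("CD",  "CG", "CB", "CA", 1.52, 112.6, 180),
    .zrow("OE1", "CD", "CG", "CB", 1.25, 118.4, 0),
    .zrow("OE2", "CD", "CG", "CB", 1.25, 118.4, 180)),
  GLY = NULL,
  HIS = rbind(
    .cb_row(),
    .zrow("CG",  "CB",  "CA", "N",  1.50, 113.8, 180),
    .zrow("ND1", "CG",  "CB", "CA", 1.38, 122.7, 90),
    .zrow("CD2", "CG",  "CB", "CA", 1.36, 131.1, -90),
    .zrow("CE1", "ND1", "CG", "CB", 1.32, 109.2, 180),
    .zrow("NE2", "CD2", "CG", "CB", 1.37, 107.2, 180)),
  ILE = rbind(
    .cb_row(1.54, 111.5),
    .zrow("CG1", "CB",  "CA", "N",  1.53, 110.4, 180),
    .zrow("CG2", "CB",  "CA", "N",  1.52, 110.5, 60),
    .zrow("CD1", "CG1", "CB", "CA", 1.51, 113.8, 180)),
  LEU = rbind(
    .cb_row(),
    .zrow("CG",  "CB", "CA", "N",  1.53, 116.3, 180),
    .zrow("CD1", "CG", "CB", "CA", 1.52, 110.5, 180),
    .zrow("CD2", "CG", "CB", "CA", 1.52, 110.5, 60)),
  LYS = rbind(
    .cb_row(),
    .zrow("CG", "CB", "CA", "N",  1.52, 114.1, 180),
    .zrow("CD", "CG", "CB", "CA", 1.52, 111.3, 180),
    .zrow("CE", "CD", "CG", "CB", 1.52, 111.3, 180),
    .zrow("NZ", "CE", "CD", "CG", 1.49, 112.0, 180)),
  MET = rbind(
    .cb_row(),
    .zrow("CG", "CB", "CA", "N",  1.52, 114.1, 180),
    .zrow("SD", "CG", "CB", "CA", 1.80, 112.7, 180),
    .zrow("CE", "SD", "CG", "CB", 1.79, 100.9, 180)),
  PHE = rbind(
    .cb_row(),
    .zrow("CG",  "CB",  "CA",  "N",  1.50, 113.8, 180),
    .zrow("CD1", "CG",  "CB",  "CA", 1.39, 120.8, -90),
    .zrow("CD2", "CG",  "CB",  "CA", 1.39, 120.8, 90),
    .zrow("CE1", "CD1", "CG",  "CB", 1.39, 120.7, 180),
    .zrow("CE2", "CD2", "CG",  "CB", 1.39, 120.7, 180),
    .zrow("CZ",  "CE1", "CD1", "CG", 1.39, 120.0, 0)),
  PRO = rbind(
    .zrow("CB", "CA", "N", "C", 1.53, 103.7, .CB_TORSION),
    .zrow("CG", "CB", "CA", "N",  1.52, 107.7, 9),
    .zrow("CD", "CG", "CB", "CA", 1.52, 108.2, -10)),
  SER = rbind(
    .cb_row(),
    .zrow("OG", "CB", "CA", "N", 1.42, 110.8, 180)),
  THR = rbind(
    .cb_row(1.54, 111.5),
    .zrow("OG1", "CB", "CA", "N", 1.43, 109.6, 180),
    .zrow("CG2", "CB", "CA", "N", 1.52, 110.5, 60)),
  TRP = rbind(
    .cb_row(),
    .zrow("CG",  "CB",  "CA",  "N",  1.50, 113.6, 180),
    .zrow("CD1", "CG",  "CB",  "CA", 1.35, 129.1, -90),
    .zrow("CD2", "CG",  "CB",  "CA", 1.45, 124.5, 90),
    .zrow("NE1", "CD1", "CG",  "CB", 1.40, 110.0, 180),
    .zrow("CE2", "NE1", "CD1", "CG", 1.37, 109.4, 0),
    .zrow("CE3", "CD2", "CG",  "CB", 1.41, 132.1, 0),
    .zrow("CZ2", "CE2", "NE1", "CD1", 1.43, 132.2, 180),
    .zrow("CZ3", "CE3", "CD2", "CG",  1.39, 117.8, 180),
    .zrow("CH2", "CZ2", "CE2", "NE1", 1.35, 116.8, 180)),
  TYR = rbind(
    .cb_row(),
    .zrow("CG",  "CB",  "CA",  "N",  1.51, 113.8, 180),
    .zrow("CD1", "CG",  "CB",  "CA", 1.39, 120.8, -90),
    .zrow("CD2", "CG",  "CB",  "CA", 1.39, 120.8, 90),
    .zrow("CE1", "CD1", "CG",  "CB", 1.39, 121.1, 180),
    .zrow("CE2", "CD2", "CG",  "CB", 1.39, 121.1, 180),
    .zrow("CZ",  "CE1", "CD1", "CG", 1.38, 119.6, 0),
    .zrow("OH",  "CZ",  "CE1", "CD1", 1.38, 119.9, 180)),
  VAL = rbind(
    .cb_row(1.54, 111.5),
    .zrow("CG1", "CB", "CA", "N", 1.52, 110.5, 180),
    .zrow("CG2", "CB", "CA", "N", 1.52, 110.5, -60))
)

# Ring-closure bonds not implied by the Z-matrix parent chain.
.RING_CLOSURES <- list(
  HIS = list(c("CE1", "NE2")),
  PHE = list(c("CZ", "CE2")),
  TYR = list(c("CZ", "CE2")),
  TRP = list(c("CE2", "CD2"), c("CH2", "CZ3")),
  PRO = list(c("CD", "N"))
)

# Hydrogen counts on side-chain heavy atoms at physiological pH:
# Asp/Glu deprotonated, Lys/Arg protonated, His neutral (the proton sits
# on NE2), Cys thiol protonated unless engaged in a declared disulfide.
.H_SIDE <- list(
  ALA = c(CB = 3),
  ARG = c(CB = 2, CG = 2, CD = 2, NE = 1, NH1 = 2, NH2 = 2),
  ASN = c(CB = 2, ND2 = 2),
  ASP = c(CB = 2),
  CYS = c(CB = 2, SG = 1),
  GLN = c(CB = 2, CG = 2, NE2 = 2),
  GLU = c(CB = 2, CG = 2),
  GLY = c(),
  HIS = c(CB = 2, CD2 = 1, CE1 = 1, NE2 = 1),
  ILE = c(CB = 1, CG1 = 2, CG2 = 3, CD1 = 3),
  LEU = c(CB = 2, CG = 1, CD1 = 3, CD2 = 3),
  LYS = c(CB = 2, CG = 2, CD = 2, CE = 2, NZ = 3),
  MET = c(CB = 2, CG = 2, CE = 3),
  PHE = c(CB = 2, CD1 = 1, CD2 = 1, CE1 = 1, CE2 = 1, CZ = 1),
  PRO = c(CB = 2, CG = 2, CD = 2),
  SER = c(CB = 2, OG = 1),
  THR = c(CB = 1, OG1 = 1, CG2 = 3),
  TRP = c(CB = 2, CD1 = 1, NE1 = 1, CE3 = 1, CZ2 = 1, CZ3 = 1, CH2 = 1),
  TYR = c(CB = 2, CD1 = 1, CD2 = 1, CE1 = 1, CE2 = 1, OH = 1),
  VAL = c(CB = 1, CG1 = 3, CG2 = 3)
)

# Formal charges used by the optional electrostatic term, spread over the
# terminal atoms of each charged group.
.Q_SIDE <- list(
  ARG = c(NH1 = 0.5, NH2 = 0.5),
  ASP = c(OD1 = -0.5, OD2 = -0.5),
  GLU = c(OE1 = -0.5, OE2 = -0.5),
  LYS = c(NZ = 1)
)

.H_BOND_LENGTH <- c(C = 1.09, N = 1.01, O = 0.96, S = 1.34)

.element_of <- function(name) substr(name, 1, 1)

# Canonical backbone geometry.
.BB <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_c_oxt = 1.25,
  a_c_n_ca = 121.7, a_n_ca_c = 111.2, a_ca_c_n = 116.2,
  a_ca_c_o = 120.8, a_o_c_n = 123.0, a_ca_c_oxt = 117.0
)

# Backbone dihedral presets for the two supported starting states.
.STATE_DIHEDRALS <- list(
  beta    = c(phi = -140, psi = 135, omega = 180),
  polypro = c(phi = -78,  psi = 149, omega = 180)
)
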