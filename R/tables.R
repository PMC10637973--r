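# Reference tables used across descriptor and interface calculations.

# Three-letter -> one-letter amino-acid codes; common modified residues map
# to their parent so sequence extraction survives MSE/phospho-residues etc.
.aa3to1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  # modified residues -> parent
  MSE = "M", SEC = "C", CSO = "C", CME = "C", OCS = "C",
  SEP = "S", TPO = "T", PTR = "Y", HYP = "P", PCA = "E",
  MLY = "K", M3L = "K", KCX = "K", PYL = "K"
)

.aa1to3 <- setNames(names(.aa3to1)[1:20], .aa3to1[1:20])

# Average masses of the free amino acids (Da); peptide mass is the sum minus
# one water (18.02 Da) per peptide bond.
.aa_mass <- c(
  A = 89.09, R = 174.20, N = 132.12, D = 133.10, C = 121.16,
  Q = 146.15, E = 147.13, G = 75.07, H = 155.15, I = 131.17,
  L = 131.17, K = 146.19, M = 149.21, F = 165.19, P = 115.13,
  S = 105.09, T = 119.12, W = 204.23, Y = 181.19, V = 117.15,
  X = 110.0
)
.water_mass <- 18.02

# Van der Waals radii (A) by element; unknown elements fall back to 1.8 A.
.vdw_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
  SE = 1.90, ZN = 1.39, CD = 1.58, MG = 1.73, CA = 2.31,
  FE = 1.63, MN = 1.61, `NA` = 2.27, K = 2.75, CU = 1.40, NI = 1.63
)
.vdw_default <- 1.8

# Theoretical maximum solvent-accessible surface areas per residue (A^2),
# Tien et al. 2013, used for relative exposure.
.max_sasa <- c(
  ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
  GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
  LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
  SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174
)

# Hydrogen-bond capable atoms by residue type.  Backbone N is a donor and
# backbone O (and OXT) an acceptor in every residue; side-chain atoms below.
# His ring nitrogens and hydroxyls can act as both.
.hb_donors <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = c("NZ"), HIS = c("ND1", "NE2"),
  ASN = c("ND2"), GLN = c("NE2"), SER = c("OG"), THR = c("OG1"),
  TYR = c("OH"), TRP = c("NE1"), CYS = c("SG")
)
.hb_acceptors <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = c("OD1"),
  GLN = c("OE1"), HIS = c("ND1", "NE2"), SER = c("OG"), THR = c("OG1"),
  TYR = c("OH"), MET = c("SD")
)

# Charged side-chain atoms for salt-bridge detection.
.basic_atoms <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = c("NZ"), HIS = c("ND1", "NE2")
)
.acidic_atoms <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2")
)

.basic_residues <- c("ARG", "LYS", "HIS")
.acidic_residues <- c("ASP", "GLU")

.water_codes <- c("HOH", "DOD", "WAT", "H2O")

# One-letter codes accepted in user-supplied sequences.
.aa_alphabet <- c(.aa3to1[1:20], "X")

.element_radius <- function(element) {
  element <- toupper(trimws(element))
  r <- .vdw_radii[element]
  r[is.na(r)] <- .vdw_default
  unname(r)
}
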