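# Element tables and residue chemistry used by network construction.

# van der Waals radii (Angstrom), FIRST-style defaults
.VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

# covalent radii (Angstrom)
.COV_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07)

# residue names accepted as protein (includes common protonation-state and
# disulfide variants emitted by protonation tools)
.PROTEIN_RESIDUES <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "HID", "HIE", "HIP", "ASH", "GLH", "CYX", "CYM", "LYN", "MSE"
)

# side-chain atoms in conjugated sp2 groups, per residue; the backbone amide
# (N, C, O, OXT) is sp2 in every residue
.SP2_SIDECHAIN <- list(
  ARG = c("NE", "CZ", "NH1", "NH2"),
  ASP = c("CG", "OD1", "OD2"),
  ASH = c("CG", "OD1", "OD2"),
  GLU = c("CD", "OE1", "OE2"),
  GLH = c("CD", "OE1", "OE2"),
  ASN = c("CG", "OD1", "ND2"),
  GLN = c("CD", "OE1", "NE2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  HID = c("CG", "ND1", "CD2", "CE1", "NE2"),
  HIE = c("CG", "ND1", "CD2", "CE1", "NE2"),
  HIP = c("CG", "ND1", "CD2", "CE1", "NE2"),
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2")
)

# charged groups forming salt bridges
.SALT_DONOR_ATOMS <- list(
  LYS = "NZ",
  ARG = c("NE", "NH1", "NH2"),
  HIP = c("ND1", "NE2")
)
.SALT_ACCEPTOR_ATOMS <- list(
  ASP = c("OD1", "OD2"),
  GLU = c("OE1", "OE2")
)

.vdw_radius <- function(element) {
  r <- .VDW_RADII[element]
  miss <- is.na(r)
  if (any(miss)) {
    warning("unknown element(s) ", paste(unique(element[miss]), collapse = ", "),
            "; using generic van der Waals radius 1.7 A")
    r[miss] <- 1.7
  }
  unname(r)
}

.cov_radius <- function(element) {
  r <- .COV_RADII[element]
  r[is.na(r)] <- 0.77
  unname(r)
}

.is_sp2_atom <- function(residue_name, atom_name) {
  if (length(atom_name) == 0) return(logical(0))
  backbone_sp2 <- atom_name %in% c("N", "C", "O", "OXT")
  side <- mapply(function(res, at) {
    s <- .SP2_SIDECHAIN[[res]]
    !is.null(s) && at %in% s
  }, residue_name, atom_name, USE.NAMES = FALSE)
  backbone_sp2 | side
}
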