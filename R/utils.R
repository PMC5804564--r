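# Shared chemical tables and small-geometry helpers.

# Covalent radii (Angstrom) for the element subset handled by the pipeline.
.covalentRadii <- c(
  H = 0.37, C = 0.77, N = 0.75, O = 0.73, S = 1.02, P = 1.06,
  F = 0.71, CL = 0.99, BR = 1.14, I = 1.33, SE = 1.16,
  FE = 1.25, ZN = 1.22, MG = 1.30, `NA` = 1.54, K = 1.96, CA = 1.74, MN = 1.39
)

# van der Waals radii for the clash check.
.vdwRadii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
  FE = 1.40, ZN = 1.39, MG = 1.73, `NA` = 2.27, K = 2.75, CA = 2.31, MN = 1.40
)

.covRadius <- function(element) {
  r <- .covalentRadii[toupper(element)]
  r[is.na(r)] <- 1.5  # permissive fallback for unlisted elements
  unname(r)
}

.vdwRadius <- function(element) {
  r <- .vdwRadii[toupper(element)]
  r[is.na(r)] <- 1.7
  unname(r)
}

# Three-letter <-> one-letter amino acid codes.
.aa3to1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)
.aa1to3 <- structure(names(.aa3to1), names = unname(.aa3to1))

.waterComps <- c("HOH", "DOD")

# Heavy sidechain atoms expected for a complete residue of each type
# (beyond N, CA, C, O).
.sidechainAtoms <- list(
  ALA = "CB",
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  CYS = c("CB", "SG"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  GLY = character(0),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG", "CD"),
  SER = c("CB", "OG"),
  THR = c("CB", "OG1", "CG2"),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  VAL = c("CB", "CG1", "CG2")
)

# Reference backbone bond lengths (Angstrom) and sigmas for the geometry check.
.backboneBondRef <- data.frame(
  a = c("N", "CA", "C", "CA"),
  b = c("CA", "C", "O", "CB"),
  length = c(1.458, 1.525, 1.231, 1.530),
  sigma = c(0.019, 0.021, 0.020, 0.020),
  stringsAsFactors = FALSE
)
.peptideBondRef <- c(length = 1.329, sigma = 0.014)

.vnorm <- function(v) sqrt(sum(v * v))
.unit <- function(v) v / .vnorm(v)
.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Signed volume of the parallelepiped spanned by (p1-c, p2-c, p3-c).
.tripleProduct <- function(ctr, p1, p2, p3) {
  sum(.cross(p1 - ctr, p2 - ctr) * (p3 - ctr))
}

# Dihedral angle in degrees for points p1-p2-p3-p4.
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross(b1, b2); n2 <- .cross(b2, b3)
  m1 <- .cross(n1, .unit(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# Natural-extension reference frame: place a new atom at the stated bond
# length, bond angle (deg, at atom c) and dihedral (deg, about b-c) given
# three prior positions a-b-c.
.placeAtom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  d2 <- c(bond * cos(pi - ang),
          -bond * cos(pi - dih) * sin(pi - ang),
          -bond * sin(pi - dih) * sin(pi - ang))
  bc <- .unit(c - b)
  n <- .unit(.cross(b - a, bc))
  m <- cbind(bc, .cross(n, bc), n)
  as.numeric(m %*% d2 + c)
}

# Pairwise squared distances between two xyz matrices (n x 3, m x 3).
.distMat <- function(x, y) {
  outer(rowSums(x^2), rep(1, nrow(y))) +
    outer(rep(1, nrow(x)), rowSums(y^2)) - 2 * x %*% t(y)
}

.xyzMatrix <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])
}

# Split a one-letter sample sequence with (XXX) inserts into per-residue
# tokens, e.g. "AG(MSE)K" -> c("A", "G", "(MSE)", "K").
.seqTokens <- function(seq) {
  if (!nzchar(seq)) return(character(0))
  out <- character(0)
  chars <- strsplit(seq, "")[[1]]
  i <- 1
  while (i <= length(chars)) {
    if (chars[i] == "(") {
      j <- i
      while (j <= length(chars) && chars[j] != ")") j <- j + 1
      if (j > length(chars)) stop("unterminated '(' in sequence")
      out <- c(out, paste(chars[i:j], collapse = ""))
      i <- j + 1
    } else {
      out <- c(out, chars[i])
      i <- i + 1
    }
  }
  out
}

# One-letter code for a residue component id ("X" for unknown components).
.comp2letter <- function(comp) {
  out <- .aa3to1[comp]
  out[is.na(out)] <- "X"
  unname(out)
}

.stopf <- function(class, fmt, ...) {
  stop(structure(class = c(class, "minidepError", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}
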