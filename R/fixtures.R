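# Fixture factory: seeded generator of every test input. Mini-CCD, PRD
# entries, reference FASTA, the Table 1 example block, and depositions
# with planted defects (including the Fig 4A tag+mutation and Fig 4C
# chimera architectures). Identical (plan, seed) inputs produce
# byte-identical outputs.

# run expr under a fixed RNG state, restoring the caller's state after
.withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (hadSeed) get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", sample.kind = "Rejection")
  expr
}

.randomSeq <- function(n, alphabet = names(.aa1to3)) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# The seeded sequence material shared by makeRefDb and makeDeposition.
.fixtureSequences <- function(seed) {
  .withSeed(seed, {
    base30 <- .randomSeq(30)
    body <- strsplit(.randomSeq(70, setdiff(names(.aa1to3), c("H", "Y", "W"))),
                     "")[[1]]
    body[55] <- "Y"
    fig4aRef <- paste(body, collapse = "")
    body[55] <- "W"
    fig4aSampleBody <- paste(body, collapse = "")
    chimA <- .randomSeq(219)
    chimB <- .randomSeq(80)
    decoy <- .randomSeq(60)
    chim <- strsplit(chimA, "")[[1]]
    chim[182:197] <- strsplit(substr(chimB, 33, 48), "")[[1]]
    list(base30 = base30, fig4aRef = fig4aRef,
         fig4aSample = paste0("GSSHHHHHH", fig4aSampleBody),
         chimA = chimA, chimB = chimB,
         chimSample = paste(chim, collapse = ""), decoy = decoy)
  })
}

# ---- ideal residue geometry (NeRF) -----------------------------------

# Backbone/sidechain internal coordinates used for every built residue.
.bbGeom <- list(nca = 1.458, cac = 1.525, co = 1.231, cn = 1.329,
                cacb = 1.530, aNCAC = 111.0, aCACO = 120.8, aCACN = 116.2,
                aCNCA = 121.7, aCCACB = 110.5, dNCCACB = 122.5)

.sidechainBonds <- list(
  ALA = data.frame(a = "CA", b = "CB", stringsAsFactors = FALSE),
  GLY = NULL,
  LEU = data.frame(a = c("CA", "CB", "CG", "CG"),
                   b = c("CB", "CG", "CD1", "CD2"), stringsAsFactors = FALSE),
  VAL = data.frame(a = c("CA", "CB", "CB"), b = c("CB", "CG1", "CG2"),
                   stringsAsFactors = FALSE),
  CYS = data.frame(a = c("CA", "CB"), b = c("CB", "SG"),
                   stringsAsFactors = FALSE)
)

.elementOf <- function(name) substr(name, 1, 1)

#' Build an ideal polypeptide backbone
#'
#' Natural-extension-reference-frame construction with ideal bond lengths
#' and angles; per-residue phi/psi set the conformation (defaults: ideal
#' alpha helix, phi -57 / psi -47). Residues carry N, CA, C, O and (except
#' glycine) CB.
#'
#' @param comps three-letter component codes, one per residue.
#' @param phi,psi backbone torsions in degrees (recycled).
#' @param chain chain id for the emitted atom records.
#' @param startSeq first residue number.
#' @return An atom-record data.frame (chain, seqNum, compId, atomName,
#'   element, x, y, z, occupancy, bFactor, altId).
#' @export
buildIdealChain <- function(comps, phi = -57, psi = -47, chain = "A",
                            startSeq = 1L) {
  n <- length(comps)
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  g <- .bbGeom
  N <- CA <- C <- vector("list", n)
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(g$nca, 0, 0)
  ang <- (180 - g$aNCAC) * pi / 180
  C[[1]] <- CA[[1]] + g$cac * c(cos(ang), sin(ang), 0)
  for (i in seq_len(n)[-1]) {
    N[[i]] <- .placeAtom(N[[i - 1]], CA[[i - 1]], C[[i - 1]], g$cn, g$aCACN,
                         psi[i - 1])
    CA[[i]] <- .placeAtom(CA[[i - 1]], C[[i - 1]], N[[i]], g$nca, g$aCNCA,
                          180)
    C[[i]] <- .placeAtom(C[[i - 1]], N[[i]], CA[[i]], g$cac, g$aNCAC,
                         phi[i])
  }
  rows <- list()
  add <- function(i, nm, p) {
    rows[[length(rows) + 1]] <<- data.frame(
      chain = chain, seqNum = startSeq + i - 1L, compId = comps[i],
      atomName = nm, element = .elementOf(nm), x = p[1], y = p[2], z = p[3],
      occupancy = 1, bFactor = 15, altId = NA_character_,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    add(i, "N", N[[i]]); add(i, "CA", CA[[i]]); add(i, "C", C[[i]])
    add(i, "O", .placeAtom(N[[i]], CA[[i]], C[[i]], g$co, g$aCACO,
                           psi[i] + 180))
    if (comps[i] != "GLY")
      add(i, "CB", .placeAtom(N[[i]], C[[i]], CA[[i]], g$cacb, g$aCCACB,
                              g$dNCCACB))
  }
  do.call(rbind, rows)
}

# One ideal residue of a component, as name/element/xyz (amino acids only).
.idealResidueAtoms <- function(comp) {
  at <- buildIdealChain(comp, chain = "X")
  pos <- stats::setNames(lapply(seq_len(nrow(at)), function(k)
    as.numeric(at[k, c("x", "y", "z")])), at$atomName)
  ext <- switch(comp,
    LEU = {
      cg <- .placeAtom(pos$N, pos$CA, pos$CB, 1.530, 113.9, 180)
      list(CG = cg,
           CD1 = .placeAtom(pos$CA, pos$CB, cg, 1.521, 110.7, 180),
           CD2 = .placeAtom(pos$CA, pos$CB, cg, 1.521, 110.7, 60))
    },
    VAL = list(CG1 = .placeAtom(pos$N, pos$CA, pos$CB, 1.521, 110.5, 180),
               CG2 = .placeAtom(pos$N, pos$CA, pos$CB, 1.521, 110.5, -60)),
    CYS = list(SG = .placeAtom(pos$N, pos$CA, pos$CB, 1.808, 114.4, 180)),
    NULL)
  pos <- c(pos, ext)
  data.frame(name = names(pos), element = .elementOf(names(pos)),
             x = vapply(pos, `[`, numeric(1), 1),
             y = vapply(pos, `[`, numeric(1), 2),
             z = vapply(pos, `[`, numeric(1), 3),
             stringsAsFactors = FALSE, row.names = NULL)
}

.compFromAtoms <- function(compId, atoms, bonds, stereoCenters = list()) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rownames(xyz) <- atoms$name
  pos <- function(nm) xyz[nm, ]
  stereo <- lapply(stereoCenters, function(sc) {
    vol <- .tripleProduct(pos(sc$center), pos(sc$neighbors[1]),
                          pos(sc$neighbors[2]), pos(sc$neighbors[3]))
    list(center = sc$center, neighbors = sc$neighbors,
         parity = if (vol >= 0) 1 else -1)
  })
  new("ChemComp", compId = compId,
      atoms = data.frame(name = atoms$name, element = atoms$element,
                         charge = 0, stringsAsFactors = FALSE),
      bonds = bonds, stereocenters = stereo, idealXyz = xyz)
}

.aminoAcidComp <- function(comp) {
  atoms <- .idealResidueAtoms(comp)
  bonds <- data.frame(a = c("N", "CA", "C"), b = c("CA", "C", "O"),
                      stringsAsFactors = FALSE)
  bonds <- rbind(bonds, .sidechainBonds[[comp]])
  bonds$order <- "single"
  stereo <- if (comp == "GLY") list() else
    list(list(center = "CA", neighbors = c("N", "C", "CB")))
  .compFromAtoms(comp, atoms, bonds, stereo)
}

.nagComp <- function() {
  ring <- c("C1", "C2", "C3", "C4", "C5", "O5")
  r <- 1.46; h <- 0.25
  pos <- list()
  for (i in seq_along(ring)) {
    a <- (i - 1) * pi / 3
    pos[[ring[i]]] <- c(r * cos(a), r * sin(a), h * (-1)^(i - 1))
  }
  radial <- function(base, extra, dz = 0) {
    p <- pos[[base]]
    d <- .unit(c(p[1], p[2], 0))
    p + extra * d + c(0, 0, dz)
  }
  pos$N2 <- radial("C2", 1.45)
  pos$C7 <- radial("C2", 2.90)
  pos$O7 <- radial("C2", 2.90, 1.40)
  pos$C8 <- radial("C2", 4.40)
  pos$O3 <- radial("C3", 1.43)
  pos$O4 <- radial("C4", 1.43)
  pos$C6 <- radial("C5", 1.50)
  pos$O6 <- radial("C5", 1.50, 1.40)
  atoms <- data.frame(name = names(pos), element = .elementOf(names(pos)),
                      x = vapply(pos, `[`, numeric(1), 1),
                      y = vapply(pos, `[`, numeric(1), 2),
                      z = vapply(pos, `[`, numeric(1), 3),
                      stringsAsFactors = FALSE, row.names = NULL)
  bonds <- data.frame(
    a = c("C1", "C2", "C3", "C4", "C5", "O5", "C2", "N2", "C7", "C7",
          "C3", "C4", "C5", "C6"),
    b = c("C2", "C3", "C4", "C5", "O5", "C1", "N2", "C7", "O7", "C8",
          "O3", "O4", "C6", "O6"),
    order = "single", stringsAsFactors = FALSE)
  .compFromAtoms("NAG", atoms, bonds, list(
    list(center = "C2", neighbors = c("C1", "C3", "N2")),
    list(center = "C3", neighbors = c("C2", "C4", "O3")),
    list(center = "C4", neighbors = c("C3", "C5", "O4")),
    list(center = "C5", neighbors = c("C4", "O5", "C6"))))
}

# 7-atom novel-ligand placeholder with one stereocenter at C1.
.mnlComp <- function() {
  d1 <- c(1, 1, 1) / sqrt(3); d2 <- c(1, -1, -1) / sqrt(3)
  d3 <- c(-1, 1, -1) / sqrt(3); d4 <- c(-1, -1, 1) / sqrt(3)
  pos <- list(C1 = c(0, 0, 0), N1 = 1.47 * d1, O1 = 1.43 * d2,
              C2 = 1.53 * d3, C3 = 1.53 * d4, C4 = 3.06 * d3,
              O2 = 2.96 * d4)
  atoms <- data.frame(name = names(pos), element = .elementOf(names(pos)),
                      x = vapply(pos, `[`, numeric(1), 1),
                      y = vapply(pos, `[`, numeric(1), 2),
                      z = vapply(pos, `[`, numeric(1), 3),
                      stringsAsFactors = FALSE, row.names = NULL)
  bonds <- data.frame(a = c("C1", "C1", "C1", "C1", "C2", "C3"),
                      b = c("N1", "O1", "C2", "C3", "C4", "O2"),
                      order = "single", stringsAsFactors = FALSE)
  .compFromAtoms("MNL", atoms, bonds,
                 list(list(center = "C1", neighbors = c("N1", "O1", "C2"))))
}

# peptide-like tripeptide (Ala-Gly-Ala) stored as a non-polymer component
.tpaComp <- function() {
  ch <- buildIdealChain(c("ALA", "GLY", "ALA"), phi = -139, psi = 135,
                        chain = "X")
  atoms <- data.frame(name = paste0(ch$atomName, ch$seqNum),
                      element = ch$element, x = ch$x, y = ch$y, z = ch$z,
                      stringsAsFactors = FALSE)
  bonds <- list()
  for (i in 1:3) {
    b <- data.frame(a = c("N", "CA", "C"), b = c("CA", "C", "O"),
                    stringsAsFactors = FALSE)
    if (ch$compId[match(i, ch$seqNum)] != "GLY")
      b <- rbind(b, data.frame(a = "CA", b = "CB"))
    b$a <- paste0(b$a, i); b$b <- paste0(b$b, i)
    bonds[[i]] <- b
  }
  bonds[[4]] <- data.frame(a = c("C1", "C2"), b = c("N2", "N3"),
                           stringsAsFactors = FALSE)
  bonds <- do.call(rbind, bonds)
  bonds$order <- "single"
  .compFromAtoms("TPA", atoms, bonds, list(
    list(center = "CA1", neighbors = c("N1", "C1", "CB1")),
    list(center = "CA3", neighbors = c("N3", "C3", "CB3"))))
}

#' Build the packaged mini chemical component dictionary
#'
#' Deterministic (no seed): ALA, GLY, LEU, VAL, CYS, HOH, NAG, the 7-atom
#' novel-ligand placeholder MNL, and the peptide-like tripeptide TPA that
#' matches the packaged PRD entry. Ideal coordinates are included for
#' every component.
#'
#' @param path optional file to write via \code{\link{writeCcd}}.
#' @return Named list of \linkS4class{ChemComp} (invisibly when written).
#' @export
makeMiniCcd <- function(path = NULL) {
  hoh <- new("ChemComp", compId = "HOH",
             atoms = data.frame(name = "O", element = "O", charge = 0,
                                stringsAsFactors = FALSE),
             bonds = data.frame(a = character(0), b = character(0),
                                order = character(0),
                                stringsAsFactors = FALSE),
             stereocenters = list(),
             idealXyz = matrix(0, 1, 3, dimnames = list("O", NULL)))
  ccd <- c(lapply(c(ALA = "ALA", GLY = "GLY", LEU = "LEU", VAL = "VAL",
                    CYS = "CYS"), .aminoAcidComp),
           list(HOH = hoh, NAG = .nagComp(), MNL = .mnlComp(),
                TPA = .tpaComp()))
  if (!is.null(path)) { writeCcd(ccd, path); return(invisible(ccd)) }
  ccd
}

#' Packaged peptide reference dictionary
#'
#' One entry: the Ala-Gly-Ala tripeptide TPA in its polymer representation
#' (ordered component sequence, standard peptide linkage).
#'
#' @return list of entries list(id, comps).
#' @export
makePrdDb <- function() {
  list(list(id = "PRD1", comps = c("ALA", "GLY", "ALA")))
}

#' Write the seeded reference-sequence database
#'
#' Five protein records: the base-deposition reference (mouse, taxonomy
#' 10090), the Fig 4A reference (mouse, tyrosine at the position the
#' sample mutates), the two Fig 4C chimera references (pairwise identity
#' at background level outside the planted segment), and an unrelated
#' decoy. One record carries the Table 1 host organism (Escherichia coli,
#' taxonomy 562).
#'
#' @param seed integer seed.
#' @param path optional FASTA output path.
#' @return data.frame as from \code{\link{readRefDb}} (invisibly when
#'   written).
#' @export
makeRefDb <- function(seed = 1, path = NULL) {
  sq <- .fixtureSequences(seed)
  db <- data.frame(
    accession = c("BASEP1", "FIG4A1", "CHIA01", "CHIB01", "DECOY1"),
    taxonomyId = c(10090L, 10090L, 9606L, 562L, 4932L),
    scientificName = c("Mus musculus", "Mus musculus", "Homo sapiens",
                       "Escherichia coli", "Saccharomyces cerevisiae"),
    sequence = c(sq$base30, sq$fig4aRef, sq$chimA, sq$chimB, sq$decoy),
    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    lines <- as.vector(rbind(
      sprintf(">%s|%d|%s", db$accession, db$taxonomyId, db$scientificName),
      db$sequence))
    writeLines(lines, path)
    return(invisible(db))
  }
  db
}

#' The Table 1 worked-example data block
#'
#' A mouse protein expressed in Escherichia coli (host taxonomy id 562)
#' from plasmid pET28a: entity, entity_poly and entity_src_gen rows linked
#' by entity id 1. Validates cleanly against the packaged core schema.
#'
#' @return A \linkS4class{DataBlock}.
#' @export
makeTable1Block <- function() {
  seq30 <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLI"
  new("DataBlock", blockId = "table1", tables = list(
    entity = data.frame(
      id = "1", type = "polymer",
      pdbx_description = "example mouse protein",
      pdbx_number_of_molecules = "1", stringsAsFactors = FALSE),
    entity_poly = data.frame(
      entity_id = "1", type = "polypeptide(L)",
      pdbx_seq_one_letter_code = seq30, pdbx_strand_id = "A",
      stringsAsFactors = FALSE),
    entity_src_gen = data.frame(
      entity_id = "1",
      pdbx_gene_src_scientific_name = "Mus musculus",
      pdbx_gene_src_ncbi_taxonomy_id = "10090",
      pdbx_host_org_scientific_name = "Escherichia coli",
      pdbx_host_org_ncbi_taxonomy_id = "562",
      pdbx_host_org_vector_type = "plasmid",
      plasmid_name = "pET28a", stringsAsFactors = FALSE)))
}

# ---- deposition generator --------------------------------------------

#' Defect-plan vocabulary
#'
#' The plantable codes: the curation issue codes the generator can plant
#' plus the architectural plans (tag_and_mutation, chimera_swap,
#' misplaced_water, ligand_missing_atom).
#'
#' @return character vector of plan codes.
#' @export
defectPlanCodes <- function() {
  c("Atomic clashes", "Atoms with unrealistic or zero occupancies",
    "Zero B-factor", "Extra hydrogen atoms",
    "Occupancy of atoms on special symmetry positions",
    "Unusual phi/psi torsion angles", "Wavelength discrepancy",
    "Missing free R test set in the structure factors",
    "Missing anisotropic B-factor", "Ligand geometry", "Ligand identity",
    "Polymer geometry", "Polymer backbone linkage", "Sequence discrepancy",
    "Chirality error", "Distant waters",
    "Missing and/or inconsistent metadata values",
    "Incomplete data in the structure factors",
    "Reported and calculated quaternary structure do not agree",
    "tag_and_mutation", "chimera_swap", "misplaced_water",
    "ligand_missing_atom")
}

# brute-force minimal distance from point p to any symmetry image of the
# polymer atoms (used to site the distant-water plant)
.minImageDist <- function(p, polyXyz, M, Minv, ops) {
  pf <- as.numeric(Minv %*% p)
  best <- Inf
  for (op in ops) for (tr in .lattice27) {
    img <- as.numeric(M %*% (op$R %*% pf + op$t + tr))
    best <- min(best, sqrt(min(.distMat(matrix(img, 1), polyXyz))))
  }
  best
}

.waterRow <- function(seqNum, p, occupancy = 1) {
  data.frame(chain = "S", seqNum = seqNum, compId = "HOH", atomName = "O",
             element = "O", x = p[1], y = p[2], z = p[3],
             occupancy = occupancy, bFactor = 20, altId = NA_character_,
             stringsAsFactors = FALSE)
}

#' Generate a deposition with planted defects
#'
#' The defect-free base is a 30-residue ideal helix (chain A, backbone +
#' CB), one MNL ligand, five waters, a P 21 cell and clean metadata
#' (Rmerge 0.13, wavelength 0.9793, free R flag present, Table 1-style
#' source rows). Each requested plan code mutates the base exactly once;
#' the manifest lists for every plant the expected finding code, its
#' severity and the locus. tag_and_mutation swaps in the Fig 4A
#' architecture (9-residue N-terminal tag, declared Y->W substitution at
#' sample position 64); chimera_swap swaps in the Fig 4C architecture
#' (219-residue sample, positions 182-197 from the second reference).
#'
#' @param plan character vector of plan codes (see
#'   \code{\link{defectPlanCodes}}).
#' @param seed integer seed (shared with \code{\link{makeRefDb}}).
#' @return list(deposition = \linkS4class{Deposition}, manifest =
#'   data.frame(plan, expectedCode, expectedSeverity, locus)).
#' @export
makeDeposition <- function(plan = character(0), seed = 1) {
  bad <- setdiff(plan, defectPlanCodes())
  if (length(bad))
    .stopf("minidepPlanError", "unknown defect plan code(s): %s",
           paste(bad, collapse = ", "))
  if (anyDuplicated(plan))
    .stopf("minidepPlanError", "each defect may be planted only once")
  sq <- .fixtureSequences(seed)
  planned <- function(code) code %in% plan
  manifest <- list()
  note <- function(planCode, expectedCode, locus) {
    manifest[[length(manifest) + 1]] <<- data.frame(
      plan = planCode, expectedCode = expectedCode,
      expectedSeverity = if (is.na(expectedCode)) NA_character_
        else unname(.issueCodes[expectedCode]),
      locus = locus, stringsAsFactors = FALSE)
  }

  # --- sample sequence / architecture
  sample <- sq$base30
  declarations <- list(declared_ligand = "MNL", oligomeric_count = "1")
  if (planned("tag_and_mutation")) {
    sample <- sq$fig4aSample
    declarations$mutation <- "Y64W"
    note("tag_and_mutation", NA_character_, "64")
  } else if (planned("chimera_swap")) {
    sample <- sq$chimSample
    note("chimera_swap", NA_character_, "182-197")
  }
  comps <- unname(.aa1to3[strsplit(sample, "")[[1]]])
  n <- length(comps)

  # --- chain geometry
  phi <- rep(-57, n); psi <- rep(-47, n)
  if (planned("Unusual phi/psi torsion angles")) {
    # psi 50 falls in the gap between the permissive helix (psi <= 45) and
    # sheet (psi >= 60) regions while bending the chain only gently
    phi[20] <- -75; psi[20] <- 50
    note("Unusual phi/psi torsion angles", "Unusual phi/psi torsion angles",
         "A:20")
  }
  chain <- buildIdealChain(comps, phi = phi, psi = psi, chain = "A")
  xyz <- .xyzMatrix(chain)
  chain[, c("x", "y", "z")] <- sweep(xyz, 2, colMeans(xyz)) +
    matrix(rep(c(12, 14, 15), each = nrow(xyz)), ncol = 3)
  if (planned("Polymer backbone linkage")) {
    # shift the tail along the helix axis: the chain separates cleanly
    # (no new contacts) while the 15-16 peptide bond stretches to ~9 A
    caM <- .xyzMatrix(chain[chain$atomName == "CA", ])
    ax <- .unit(caM[nrow(caM), ] - caM[1, ])
    sel <- chain$seqNum >= 16
    chain[sel, c("x", "y", "z")] <-
      sweep(.xyzMatrix(chain)[sel, , drop = FALSE], 2, -8 * ax)
    note("Polymer backbone linkage", "Polymer backbone linkage", "A:15-16")
  }
  if (planned("Sequence discrepancy")) {
    target <- if (comps[10] == "ALA") "GLY" else "ALA"
    sel <- chain$seqNum == 10
    chain$compId[sel] <- target
    if (target == "GLY") chain <- chain[!(sel & chain$atomName == "CB"), ]
    note("Sequence discrepancy", "Sequence discrepancy", "A:10")
  }

  cell <- list(a = 40, b = 50, c = 60, alpha = 90, beta = 90, gamma = 90)
  spaceGroup <- if (planned(
    "Occupancy of atoms on special symmetry positions")) "P 2" else "P 21"

  caOf <- function(s) as.numeric(
    chain[chain$seqNum == s & chain$atomName == "CA", c("x", "y", "z")])

  # radial direction off the local helix axis, so placements clear both
  # the chain termini and the neighboring turns
  centroid <- colMeans(.xyzMatrix(chain))
  caAll <- .xyzMatrix(chain[chain$atomName == "CA", ])
  axis <- .unit(caAll[nrow(caAll), ] - caAll[1, ])
  outward <- function(s, dist) {
    ca <- caOf(s)
    v <- ca - centroid
    ca + dist * .unit(v - sum(v * axis) * axis)
  }

  # rigid translation placing a radial site near residue 5 exactly on a
  # P 2 two-fold axis (fractional x = 1/2, z = 1/2 runs along y)
  specialWater <- NULL
  if (planned("Occupancy of atoms on special symmetry positions")) {
    w0 <- outward(5, 4.0)
    t <- c(20 - w0[1], 0, 30 - w0[3])
    chain[, c("x", "y", "z")] <- sweep(.xyzMatrix(chain), 2, -t)
    centroid <- centroid + t
    specialWater <- w0 + t
  }

  # --- ligand
  mnl <- .mnlComp()
  ligXyz <- mnl@idealXyz
  if (planned("Chirality error")) {
    ligXyz[, 1] <- -ligXyz[, 1]   # mirror image: same graph, opposite parity
    note("Chirality error", "Chirality error", "L:1")
  }
  if (planned("Ligand geometry")) {
    d <- .unit(ligXyz["C4", ] - ligXyz["C2", ])
    ligXyz["C4", ] <- ligXyz["C4", ] + 0.15 * d
    note("Ligand geometry", "Ligand geometry", "L:1")
  }
  ligXyz <- sweep(ligXyz, 2, -outward(15, 8.5))   # C1 was at the origin
  ligNames <- rownames(mnl@idealXyz)
  keepLig <- rep(TRUE, length(ligNames))
  if (planned("ligand_missing_atom")) {
    keepLig[ligNames == "C4"] <- FALSE
    note("ligand_missing_atom", "ligand_partial_match", "L:1")
  }
  ligand <- data.frame(
    chain = "L", seqNum = 1L, compId = "MNL", atomName = ligNames[keepLig],
    element = mnl@atoms$element[keepLig], x = ligXyz[keepLig, 1],
    y = ligXyz[keepLig, 2], z = ligXyz[keepLig, 3], occupancy = 1,
    bFactor = 25, altId = NA_character_, stringsAsFactors = FALSE)
  if (planned("Ligand identity")) {
    declarations$declared_ligand <- "NAG"
    note("Ligand identity", "Ligand identity", "L:1")
  }

  # --- waters
  waterAnchors <- c(3, 8, 13, 18, 23)
  waters <- do.call(rbind, lapply(seq_along(waterAnchors), function(k)
    .waterRow(k, outward(waterAnchors[k], 4.6))))
  M <- cellOrthoMatrix(cell); Minv <- solve(M)
  ops <- spaceGroupOps(spaceGroup)
  polyXyz <- .xyzMatrix(chain)
  if (planned("Atomic clashes")) {
    # 2.3 A from the carbonyl O of residue 10: inside the O..O clash
    # limit (2.64 A) but well outside the covalent-bond window (1.91 A)
    oSel <- chain$seqNum == 10 & chain$atomName == "O"
    cSel <- chain$seqNum == 10 & chain$atomName == "C"
    o10 <- as.numeric(chain[oSel, c("x", "y", "z")])
    c10 <- as.numeric(chain[cSel, c("x", "y", "z")])
    waters[1, c("x", "y", "z")] <- as.list(o10 + 2.3 * .unit(o10 - c10))
    note("Atomic clashes", "Atomic clashes", "A:10|S:1")
  }
  if (planned("Distant waters")) {
    grid <- seq(0.1, 0.9, by = 0.1)
    cands <- expand.grid(x = grid, y = grid, z = grid)
    pos <- NULL
    for (k in seq_len(nrow(cands))) {
      p <- as.numeric(M %*% as.numeric(cands[k, ]))
      idDist <- sqrt(min(.distMat(matrix(p, 1), polyXyz)))
      if (idDist <= 6) next
      best <- .minImageDist(p, polyXyz, M, Minv, ops)
      # far from every image, and already at its optimal image so the
      # repositioning step leaves it in place
      if (best > 6 && idDist - best < 1e-9) { pos <- p; break }
    }
    if (is.null(pos))
      .stopf("minidepPlanError", "no distant-water site found")
    waters[2, c("x", "y", "z")] <- as.list(pos)
    note("Distant waters", "Distant waters", "S:2")
  }
  if (planned("misplaced_water")) {
    # send water 3 to a symmetry image that is not the closest one
    w <- as.numeric(waters[3, c("x", "y", "z")])
    img <- as.numeric(M %*% (ops[[2]]$R %*% (Minv %*% w) + ops[[2]]$t +
                               c(1, 0, 0)))
    waters[3, c("x", "y", "z")] <- as.list(img)
    note("misplaced_water", "water_moved", "S:3")
  }
  if (planned("Occupancy of atoms on special symmetry positions")) {
    waters <- rbind(waters, .waterRow(6L, specialWater, occupancy = 0.75))
    note("Occupancy of atoms on special symmetry positions",
         "Occupancy of atoms on special symmetry positions", "S:6")
  }

  atoms <- rbind(chain, ligand, waters)

  # --- per-atom tweaks
  if (planned("Zero B-factor")) {
    atoms$bFactor[atoms$chain == "A" & atoms$seqNum == 5 &
                    atoms$atomName == "CA"] <- 0
    note("Zero B-factor", "Zero B-factor", "A:5:CA")
  }
  if (planned("Atoms with unrealistic or zero occupancies")) {
    atoms$occupancy[atoms$chain == "A" & atoms$seqNum == 7 &
                      atoms$atomName == "CA"] <- 0
    note("Atoms with unrealistic or zero occupancies",
         "Atoms with unrealistic or zero occupancies", "A:7:CA")
  }
  if (planned("Extra hydrogen atoms")) {
    atoms <- rbind(atoms, data.frame(
      chain = "A", seqNum = 20L, compId = atoms$compId[
        atoms$chain == "A" & atoms$seqNum == 20][1],
      atomName = "HX", element = "H", x = outward(20, 2.7)[1],
      y = outward(20, 2.7)[2], z = outward(20, 2.7)[3], occupancy = 1,
      bFactor = 15, altId = NA_character_, stringsAsFactors = FALSE))
    note("Extra hydrogen atoms", "Extra hydrogen atoms", "A:20:HX")
  }
  if (planned("Polymer geometry")) {
    sel <- atoms$chain == "A" & atoms$seqNum == 12
    ca <- as.numeric(atoms[sel & atoms$atomName == "CA", c("x", "y", "z")])
    cb <- as.numeric(atoms[sel & atoms$atomName == "CB", c("x", "y", "z")])
    atoms[sel & atoms$atomName == "CB", c("x", "y", "z")] <-
      as.list(cb + 0.15 * .unit(cb - ca))
    note("Polymer geometry", "Polymer geometry", "A:12")
  }

  # --- metadata
  rmerge <- "0.13"
  wavelengthRefl <- "0.9793"
  freeR <- "Y"
  completeness <- "98.5"
  hostTax <- "562"
  if (planned("Wavelength discrepancy")) {
    wavelengthRefl <- "1.5418"
    note("Wavelength discrepancy", "Wavelength discrepancy",
         "reflns.pdbx_wavelength")
  }
  if (planned("Missing free R test set in the structure factors")) {
    freeR <- "N"
    note("Missing free R test set in the structure factors",
         "Missing free R test set in the structure factors",
         "reflns.pdbx_R_free_flag_present")
  }
  if (planned("Incomplete data in the structure factors")) {
    completeness <- "62.0"
    note("Incomplete data in the structure factors",
         "Incomplete data in the structure factors",
         "reflns.pdbx_completeness")
  }
  if (planned("Missing and/or inconsistent metadata values")) {
    hostTax <- "?"
    note("Missing and/or inconsistent metadata values",
         "Missing and/or inconsistent metadata values",
         "entity_src_gen[1]")
  }
  if (planned("Missing anisotropic B-factor")) {
    declarations$anisotropic_refinement <- "yes"
    note("Missing anisotropic B-factor", "Missing anisotropic B-factor",
         "atom_site_anisotrop")
  }
  if (planned("Reported and calculated quaternary structure do not agree")) {
    declarations$oligomeric_count <- "2"
    note("Reported and calculated quaternary structure do not agree",
         "Reported and calculated quaternary structure do not agree",
         "assembly")
  }

  declRows <- data.frame(
    kind = rep(names(declarations),
               vapply(declarations, length, integer(1))),
    value = unlist(declarations, use.names = FALSE),
    stringsAsFactors = FALSE)
  meta <- list(
    entity = data.frame(
      id = c("1", "2", "3"), type = c("polymer", "non-polymer", "water"),
      pdbx_description = c("fixture protein", "novel ligand MNL", "water"),
      pdbx_number_of_molecules = c("1", "1",
                                   as.character(nrow(waters))),
      stringsAsFactors = FALSE),
    entity_poly = data.frame(
      entity_id = "1", type = "polypeptide(L)",
      pdbx_seq_one_letter_code = sample, pdbx_strand_id = "A",
      stringsAsFactors = FALSE),
    entity_src_gen = data.frame(
      entity_id = "1",
      pdbx_gene_src_scientific_name = "Mus musculus",
      pdbx_gene_src_ncbi_taxonomy_id = "10090",
      pdbx_host_org_scientific_name = "Escherichia coli",
      pdbx_host_org_ncbi_taxonomy_id = hostTax,
      pdbx_host_org_vector_type = "plasmid",
      plasmid_name = "pET28a", stringsAsFactors = FALSE),
    cell = data.frame(
      length_a = "40", length_b = "50", length_c = "60",
      angle_alpha = "90", angle_beta = "90", angle_gamma = "90",
      stringsAsFactors = FALSE),
    symmetry = data.frame(`space_group_name_H-M` = spaceGroup,
                          check.names = FALSE, stringsAsFactors = FALSE),
    reflns = data.frame(
      pdbx_Rmerge_I_obs = rmerge, pdbx_wavelength = wavelengthRefl,
      pdbx_R_free_flag_present = freeR, pdbx_completeness = completeness,
      d_resolution_high = "1.8", stringsAsFactors = FALSE),
    exptl = data.frame(method = "X-RAY DIFFRACTION",
                       stringsAsFactors = FALSE),
    diffrn_radiation_wavelength = data.frame(
      id = "1", wavelength = "0.9793", stringsAsFactors = FALSE),
    pdbx_struct_oper_list = data.frame(
      id = "1",
      `matrix[1][1]` = "1", `matrix[1][2]` = "0", `matrix[1][3]` = "0",
      `matrix[2][1]` = "0", `matrix[2][2]` = "1", `matrix[2][3]` = "0",
      `matrix[3][1]` = "0", `matrix[3][2]` = "0", `matrix[3][3]` = "1",
      `vector[1]` = "0", `vector[2]` = "0", `vector[3]` = "0",
      check.names = FALSE, stringsAsFactors = FALSE),
    minidep_declaration = declRows)

  rownames(atoms) <- NULL
  dep <- new("Deposition", depId = sprintf("D_%06d", seed),
             atoms = atoms,
             sampleSequences = c(A = sample),
             metadata = new("DataBlock", blockId = sprintf("D_%06d", seed),
                            tables = meta),
             assemblyOps = list(list(id = "1", R = diag(3), t = c(0, 0, 0))),
             declarations = declarations)
  manifest <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(plan = character(0), expectedCode = character(0),
               expectedSeverity = character(0), locus = character(0),
               stringsAsFactors = FALSE)
  list(deposition = dep, manifest = manifest)
}
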