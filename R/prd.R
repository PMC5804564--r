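# Peptide reference dictionary (PRD) matching and transformation between
# polymer and non-polymer representations of peptide-like small molecules.
#
# A molecule here is a light container:
#   list(form = "polymer",    residues = data.frame(idx, comp),
#        atoms = data.frame(name, element, x, y, z, resIdx), bonds)
#   list(form = "non-polymer", atoms = data.frame(name, element, x, y, z),
#        bonds = data.frame(a, b))
# Bonds are perceived or carried over; in polymer form consecutive residues
# are joined by peptide C-N bonds.

#' Build a molecule container from atom records
#'
#' @param atoms atom records of the instance (one residue for non-polymer
#'   form; a whole peptide chain for polymer form).
#' @param form "non-polymer" or "polymer".
#' @return A molecule list (see details in \code{\link{matchPrd}}).
#' @export
asMolecule <- function(atoms, form = c("non-polymer", "polymer")) {
  form <- match.arg(form)
  if (form == "non-polymer") {
    g <- perceiveGraph(atoms)
    return(list(form = form, atoms = g@atoms, bonds = g@edges))
  }
  rs <- .residues(atoms)
  res <- data.frame(idx = seq_along(rs),
                    comp = vapply(rs, function(r) r$compId, character(1)),
                    stringsAsFactors = FALSE)
  atomRows <- list(); bondRows <- list()
  for (i in seq_along(rs)) {
    g <- perceiveGraph(rs[[i]]$atoms)
    a <- g@atoms; a$resIdx <- i
    atomRows[[i]] <- a
    if (nrow(g@edges)) {
      e <- g@edges
      e$a <- paste0(e$a, "@", i); e$b <- paste0(e$b, "@", i)
      bondRows[[length(bondRows) + 1]] <- e
    }
    if (i > 1) bondRows[[length(bondRows) + 1]] <-
        data.frame(a = paste0("C@", i - 1), b = paste0("N@", i),
                   stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, atomRows)
  atoms$name <- paste0(atoms$name, "@", atoms$resIdx)
  list(form = form, residues = res, atoms = atoms,
       bonds = do.call(rbind, bondRows))
}

#' Match a peptide-like molecule against the peptide reference dictionary
#'
#' A PRD entry retains one overall definition for a peptide-like small
#' molecule across its polymer and non-polymer representations: the
#' ordered component sequence plus the standard peptide linkage. A
#' polymer-form molecule matches when its component sequence equals an
#' entry's; a non-polymer molecule is first transformed to polymer form,
#' so both representations of one molecule yield the same PRD id.
#'
#' @param molecule a molecule list (see \code{\link{asMolecule}}).
#' @param prdDb list of entries list(id, comps) as returned by
#'   \code{\link{makePrdDb}}.
#' @param ccd CCD (required to transform non-polymer input).
#' @return The PRD id, or NULL when nothing matches.
#' @export
matchPrd <- function(molecule, prdDb, ccd = NULL) {
  if (molecule$form == "non-polymer") {
    if (is.null(ccd))
      .stopf("minidepArgumentError", "ccd required for non-polymer input")
    molecule <- tryCatch(
      transformRepresentation(molecule, "to_polymer", ccd),
      minidepTransformRefused = function(e) NULL)
    if (is.null(molecule)) return(NULL)
  }
  comps <- molecule$residues$comp
  for (entry in prdDb)
    if (identical(entry$comps, comps)) return(entry$id)
  NULL
}

# candidate peptide bonds: C-N edges where the carbon also carries an
# oxygen neighbor and a carbon neighbor (a carbonyl carbon).
.peptideBondCandidates <- function(atoms, bonds) {
  el <- stats::setNames(toupper(atoms$element), atoms$name)
  adj <- .adjacency(atoms$name, bonds)
  keep <- logical(nrow(bonds))
  cSide <- nSide <- character(nrow(bonds))
  for (k in seq_len(nrow(bonds))) {
    a <- bonds$a[k]; b <- bonds$b[k]
    pair <- c(el[[a]], el[[b]])
    if (setequal(pair, c("C", "N"))) {
      cAtom <- if (el[[a]] == "C") a else b
      nAtom <- if (el[[a]] == "C") b else a
      nb <- adj[[cAtom]]
      if (any(el[nb] == "O") && any(el[nb] == "C")) {
        keep[k] <- TRUE; cSide[k] <- cAtom; nSide[k] <- nAtom
      }
    }
  }
  data.frame(c = cSide[keep], n = nSide[keep], stringsAsFactors = FALSE)
}

.connectedComponents <- function(names, edges) {
  comp <- stats::setNames(rep(NA_integer_, length(names)), names)
  adj <- .adjacency(names, edges)
  cur <- 0
  for (nm in names) {
    if (!is.na(comp[[nm]])) next
    cur <- cur + 1
    frontier <- nm
    while (length(frontier)) {
      comp[frontier] <- cur
      frontier <- setdiff(unique(unlist(adj[frontier])),
                          names(comp)[!is.na(comp)])
    }
  }
  comp
}

#' Transform a molecule between polymer and non-polymer representations
#'
#' to_polymer: the ligand graph must partition, by cutting peptide C-N
#' bonds, into fragments each isomorphic to a CCD amino-acid component
#' joined in a linear chain; the finest such partition is chosen. A graph
#' that cannot be partitioned raises a transform_refused error naming the
#' offending atoms. to_non_polymer: residues are merged back into one
#' component graph. Atom count is conserved and a round trip restores an
#' isomorphic graph.
#'
#' @param molecule a molecule list.
#' @param direction "to_polymer" or "to_non_polymer".
#' @param ccd CCD used to recognize amino-acid fragments.
#' @return The transformed molecule.
#' @export
transformRepresentation <- function(molecule,
                                    direction = c("to_polymer",
                                                  "to_non_polymer"),
                                    ccd) {
  direction <- match.arg(direction)
  if (direction == "to_non_polymer") {
    stopifnot(molecule$form == "polymer")
    atoms <- molecule$atoms
    out <- atoms[, c("name", "element", "x", "y", "z")]
    return(list(form = "non-polymer", atoms = out, bonds = molecule$bonds))
  }
  stopifnot(molecule$form == "non-polymer")
  atoms <- molecule$atoms; bonds <- molecule$bonds
  cand <- .peptideBondCandidates(atoms, bonds)
  aaComps <- ccd[names(ccd) %in% names(.sidechainAtoms)]
  matchFragment <- function(fragNames) {
    fa <- atoms[atoms$name %in% fragNames, , drop = FALSE]
    fb <- bonds[bonds$a %in% fragNames & bonds$b %in% fragNames, ,
                drop = FALSE]
    for (comp in aaComps) {
      if (nrow(comp@atoms) != nrow(fa) || nrow(comp@bonds) != nrow(fb)) next
      maps <- .subgraphMappings(fa, fb, comp@atoms, comp@bonds)
      if (length(maps))
        return(list(comp = comp@compId,
                    mapping = .canonicalMapping(maps, fa$name)))
    }
    NULL
  }
  best <- NULL
  nc <- nrow(cand)
  if (nc > 12)
    .stopf("minidepTransformRefused",
           "too many candidate peptide bonds (%d) to partition", nc)
  for (mask in rev(seq_len(2^nc) - 1)) {   # prefer cutting more bonds
    cutIdx <- which(bitwAnd(mask, 2^(seq_len(nc) - 1)) > 0)
    if (!is.null(best) && length(cutIdx) + 1 <= length(best$frags)) next
    cut <- cand[cutIdx, , drop = FALSE]
    keepBonds <- bonds[!(paste(bonds$a, bonds$b) %in%
                           c(paste(cut$c, cut$n), paste(cut$n, cut$c))), ,
                       drop = FALSE]
    compIdx <- .connectedComponents(atoms$name, keepBonds)
    frags <- split(names(compIdx), compIdx)
    matches <- lapply(frags, matchFragment)
    if (any(vapply(matches, is.null, logical(1)))) next
    # linear order: each cut edge orders the C-side fragment first
    if (length(frags) > 1) {
      fragOf <- compIdx
      succ <- stats::setNames(rep(NA_integer_, length(frags)),
                              names(frags))
      pred <- succ
      ok <- TRUE
      for (k in seq_len(nrow(cut))) {
        fc <- as.character(fragOf[[cut$c[k]]])
        fn <- as.character(fragOf[[cut$n[k]]])
        if (fc == fn || !is.na(succ[[fc]]) || !is.na(pred[[fn]])) {
          ok <- FALSE; break
        }
        succ[[fc]] <- as.integer(fn); pred[[fn]] <- as.integer(fc)
      }
      if (!ok) next
      start <- names(pred)[is.na(pred)]
      if (length(start) != 1) next
      order <- start
      while (!is.na(succ[[order[length(order)]]]))
        order <- c(order, as.character(succ[[order[length(order)]]]))
      if (length(order) != length(frags)) next
    } else order <- names(frags)
    best <- list(frags = frags[order], matches = matches[order])
    if (length(best$frags) == nc + 1) break  # all candidates cut: finest
  }
  if (is.null(best)) {
    offending <- atoms$name
    cond <- structure(
      class = c("minidepTransformRefused", "minidepError", "error",
                "condition"),
      list(message = sprintf(
        "cannot partition ligand into amino-acid components (atoms: %s)",
        paste(offending, collapse = ", ")), call = sys.call(),
        offendingAtoms = offending))
    stop(cond)
  }
  res <- data.frame(idx = seq_along(best$frags),
                    comp = vapply(best$matches, function(m) m$comp,
                                  character(1)),
                    stringsAsFactors = FALSE, row.names = NULL)
  atomRows <- list(); bondRows <- list()
  for (i in seq_along(best$frags)) {
    frag <- best$frags[[i]]
    m <- best$matches[[i]]$mapping   # old name -> component atom name
    fa <- atoms[match(frag, atoms$name), , drop = FALSE]
    fa$resIdx <- i
    newNames <- stats::setNames(paste0(m[fa$name], "@", i), fa$name)
    fb <- bonds[bonds$a %in% frag & bonds$b %in% frag, , drop = FALSE]
    fb$a <- unname(newNames[fb$a]); fb$b <- unname(newNames[fb$b])
    fa$name <- unname(newNames[fa$name])
    atomRows[[i]] <- fa
    bondRows[[length(bondRows) + 1]] <- fb
    if (i > 1) bondRows[[length(bondRows) + 1]] <-
        data.frame(a = paste0("C@", i - 1), b = paste0("N@", i),
                   stringsAsFactors = FALSE)
  }
  list(form = "polymer", residues = res, atoms = do.call(rbind, atomRows),
       bonds = do.call(rbind, bondRows))
}
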