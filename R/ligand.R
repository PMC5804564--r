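# Ligand identification: distance-based bond perception, element-labelled
# sub-graph isomorphism against the chemical component dictionary (CCD),
# match scoring, atom-name standardization, chirality checking and
# registration of new components.

#' PerceivedGraph: a bond graph perceived from coordinates
#'
#' @slot atoms data.frame with columns name, element, x, y, z.
#' @slot edges data.frame with columns a, b (unordered atom-name pairs).
#' @slot locus source locus string.
#' @export
setClass("PerceivedGraph", representation(
  atoms = "data.frame", edges = "data.frame", locus = "character"
), prototype(locus = NA_character_))

setMethod("show", "PerceivedGraph", function(object) {
  cat(sprintf("PerceivedGraph: %d atoms, %d edges (%s)\n",
              nrow(object@atoms), nrow(object@edges), object@locus))
})

#' Perceive covalent bonds from interatomic distances
#'
#' Two atoms are bonded when their distance does not exceed the sum of
#' their covalent radii plus a tolerance (default 0.45 Angstrom, packaged
#' radius table). Hydrogens are excluded by default. The edge set is
#' deterministic for a given coordinate set.
#'
#' @param atoms atom records (data.frame with atomName or name, element,
#'   x, y, z columns), typically one residue.
#' @param tolerance distance slack in Angstrom.
#' @param includeHydrogens keep hydrogen atoms in the graph.
#' @param locus optional locus label.
#' @return A \linkS4class{PerceivedGraph}.
#' @export
perceiveGraph <- function(atoms, tolerance = 0.45, includeHydrogens = FALSE,
                          locus = NA_character_) {
  if ("atomName" %in% names(atoms)) {
    if ("seqNum" %in% names(atoms)) atoms <- .dedupAlt(atoms)
    atoms <- data.frame(name = atoms$atomName, element = atoms$element,
                        x = atoms$x, y = atoms$y, z = atoms$z,
                        stringsAsFactors = FALSE)
  }
  if (!includeHydrogens)
    atoms <- atoms[toupper(atoms$element) != "H", , drop = FALSE]
  if (!nrow(atoms)) .stopf("minidepPerceptionError", "no atoms to perceive")
  if (!all(is.finite(.xyzMatrix(atoms))))
    .stopf("minidepPerceptionError", "non-finite coordinates")
  n <- nrow(atoms)
  edges <- data.frame(a = character(0), b = character(0),
                      stringsAsFactors = FALSE)
  if (n > 1) {
    xyz <- .xyzMatrix(atoms)
    d2 <- .distMat(xyz, xyz)
    r <- .covRadius(atoms$element)
    cut <- outer(r, r, "+") + tolerance
    pairs <- which(upper.tri(d2) & d2 < 0.01^2, arr.ind = TRUE)
    if (nrow(pairs))
      .stopf("minidepPerceptionError",
             "atoms %s and %s are closer than 0.01 A",
             atoms$name[pairs[1, 1]], atoms$name[pairs[1, 2]])
    hit <- which(upper.tri(d2) & d2 <= cut^2, arr.ind = TRUE)
    if (nrow(hit))
      edges <- data.frame(a = atoms$name[hit[, 1]], b = atoms$name[hit[, 2]],
                          stringsAsFactors = FALSE)
  }
  new("PerceivedGraph", atoms = atoms, edges = edges, locus = locus)
}

# Adjacency list (name -> character vector of neighbor names).
.adjacency <- function(names, edges) {
  adj <- lapply(stats::setNames(vector("list", length(names)), names),
                function(x) character(0))
  for (k in seq_len(nrow(edges))) {
    a <- edges$a[k]; b <- edges$b[k]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# All injective mappings of the pattern graph into the target graph that
# preserve element labels and carry every pattern edge onto a target edge
# (monomorphism; the pattern may be disconnected). Backtracking with
# element/degree pruning; enumeration capped at maxMaps.
.subgraphMappings <- function(pAtoms, pEdges, tAtoms, tEdges,
                              maxMaps = 10000L) {
  np <- nrow(pAtoms)
  if (np == 0 || np > nrow(tAtoms)) return(list())
  pAdj <- .adjacency(pAtoms$name, pEdges)
  tAdj <- .adjacency(tAtoms$name, tEdges)
  pDeg <- lengths(pAdj)[pAtoms$name]
  tDeg <- lengths(tAdj)[tAtoms$name]
  pEl <- stats::setNames(toupper(pAtoms$element), pAtoms$name)
  tEl <- stats::setNames(toupper(tAtoms$element), tAtoms$name)
  # order: highest degree first, then prefer nodes adjacent to placed ones
  order <- character(0)
  remaining <- pAtoms$name[order(-pDeg, pAtoms$name)]
  while (length(remaining)) {
    nxt <- remaining[vapply(remaining, function(nm)
      any(pAdj[[nm]] %in% order), logical(1))]
    pick <- if (length(nxt)) nxt[1] else remaining[1]
    order <- c(order, pick)
    remaining <- setdiff(remaining, pick)
  }
  maps <- list()
  assign <- character(0)  # names: pattern atoms; values: target atoms
  recurse <- function(depth) {
    if (length(maps) >= maxMaps) return()
    if (depth > np) { maps[[length(maps) + 1]] <<- assign; return() }
    p <- order[depth]
    placedNbr <- intersect(pAdj[[p]], names(assign))
    cand <- if (length(placedNbr)) {
      Reduce(intersect, lapply(placedNbr, function(q) tAdj[[assign[[q]]]]))
    } else tAtoms$name
    cand <- setdiff(cand, assign)
    cand <- cand[tEl[cand] == pEl[[p]] & tDeg[cand] >= pDeg[[p]]]
    for (t in cand) {
      assign[[p]] <<- t
      recurse(depth + 1)
      assign <<- assign[names(assign) != p]
      if (length(maps) >= maxMaps) return()
    }
  }
  recurse(1)
  maps
}

# Deterministic canonical mapping: pattern atoms in sorted name order; pick
# the mapping whose target-name vector is lexicographically smallest.
.canonicalMapping <- function(maps, patternNames) {
  keyOrder <- sort(patternNames)
  keys <- vapply(maps, function(m) paste(m[keyOrder], collapse = "\r"),
                 character(1))
  m <- maps[[order(keys)[1]]]
  m[keyOrder]
}

#' Search the chemical component dictionary for a perceived instance
#'
#' A component is a hit when the element-labelled instance graph is
#' sub-graph-isomorphic to the component graph, so partially modeled
#' ligands still find their component. The match score is
#' (mapped atoms + mapped bonds) / (component atoms + component bonds);
#' exact isomorphism scores 1. Results are ranked by score (descending),
#' ties broken by component id; among automorphic mappings the
#' lexicographically smallest is kept, so the result is deterministic.
#'
#' @param graph a \linkS4class{PerceivedGraph}.
#' @param ccd named list of \linkS4class{ChemComp}.
#' @param top keep at most this many hits.
#' @return list of \linkS4class{MatchResult}, best first (empty when
#'   nothing matches, which routes the instance to new-component
#'   registration).
#' @export
searchCcd <- function(graph, ccd, top = Inf) {
  if (!length(ccd)) .stopf("minidepArgumentError", "empty CCD")
  hits <- list()
  for (comp in ccd) {
    maps <- .subgraphMappings(graph@atoms, graph@edges,
                              comp@atoms, comp@bonds)
    if (!length(maps)) next
    mapping <- .canonicalMapping(maps, graph@atoms$name)
    score <- (nrow(graph@atoms) + nrow(graph@edges)) /
      (nrow(comp@atoms) + nrow(comp@bonds))
    hits[[length(hits) + 1]] <- new(
      "MatchResult", compId = comp@compId, score = score, mapping = mapping,
      unmatchedComponentAtoms = setdiff(comp@atoms$name, mapping),
      discrepancies = emptyFindings())
  }
  if (!length(hits)) return(list())
  ord <- order(-vapply(hits, function(h) h@score, numeric(1)),
               vapply(hits, function(h) h@compId, character(1)))
  utils::head(hits[ord], top)
}

#' Standardize instance atom names to the matched component's nomenclature
#'
#' @param graph a \linkS4class{PerceivedGraph}.
#' @param match a \linkS4class{MatchResult} whose score reaches the
#'   acceptance threshold (default 1.0: automatic renaming only on exact
#'   matches).
#' @param threshold minimum score for automatic application.
#' @return A named character renaming map (old name -> component name);
#'   already-standard instances yield the identity map.
#' @export
standardizeAtoms <- function(graph, match, threshold = 1.0) {
  if (match@score < threshold)
    .stopf("minidepMatchError",
           "match score %.3f below acceptance threshold %.3f",
           match@score, threshold)
  m <- match@mapping[graph@atoms$name]
  names(m) <- graph@atoms$name
  if (anyDuplicated(m))
    .stopf("minidepMatchError", "renaming map is not injective")
  m
}

#' Check stereocenter handedness against the component definition
#'
#' For each stereocenter of the matched component, the sign of the triple
#' product of the vectors from the center to its first three ordered
#' neighbors is compared with the component's stored parity. An opposite
#' sign raises a "Chirality error"; a near-planar center (|volume| below
#' volumeTol, default 0.1 cubic Angstrom) is reported as indeterminate;
#' centers whose neighbors are not all mapped are skipped with an info
#' finding.
#'
#' @param residueAtoms instance atom records (data.frame).
#' @param comp the matched \linkS4class{ChemComp}.
#' @param mapping named character instance atom -> component atom.
#' @param volumeTol indeterminacy threshold (cubic Angstrom).
#' @return A findings data.frame.
#' @export
checkChirality <- function(residueAtoms, comp, mapping, volumeTol = 0.1) {
  if ("atomName" %in% names(residueAtoms))
    residueAtoms <- data.frame(name = residueAtoms$atomName,
                               x = residueAtoms$x, y = residueAtoms$y,
                               z = residueAtoms$z, stringsAsFactors = FALSE)
  inv <- stats::setNames(names(mapping), mapping)  # comp -> instance
  xyz <- function(instName) {
    k <- match(instName, residueAtoms$name)
    if (is.na(k)) NULL else as.numeric(residueAtoms[k, c("x", "y", "z")])
  }
  out <- list()
  for (sc in comp@stereocenters) {
    needed <- c(sc$center, sc$neighbors[1:3])
    instNames <- inv[needed]
    if (any(is.na(instNames))) {
      out <- c(out, list(finding(
        "skipped_stereocenter",
        sprintf("stereocenter %s of %s skipped: neighbor not mapped",
                sc$center, comp@compId))))
      next
    }
    pts <- lapply(instNames, xyz)
    if (any(vapply(pts, is.null, logical(1)))) {
      out <- c(out, list(finding(
        "skipped_stereocenter",
        sprintf("stereocenter %s of %s skipped: atom missing", sc$center,
                comp@compId))))
      next
    }
    v <- .tripleProduct(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
    if (abs(v) < volumeTol) {
      out <- c(out, list(finding(
        "indeterminate_chirality",
        sprintf("stereocenter %s of %s is near-planar (volume %.3f A^3)",
                sc$center, comp@compId, v),
        locus = unname(instNames[1]))))
    } else if (sign(v) != sc$parity) {
      out <- c(out, list(finding(
        "Chirality error",
        sprintf("stereocenter %s of %s has inverted handedness", sc$center,
                comp@compId),
        locus = unname(instNames[1]))))
    }
  }
  .bindFindingsList(out)
}

#' Register a new chemical component
#'
#' Used when no exact CCD hit exists: the perceived graph becomes a new
#' component with single bond orders (flagged for curator review). A
#' proposed id that is already taken, or a graph isomorphic to an existing
#' component, is refused.
#'
#' @param graph a \linkS4class{PerceivedGraph}.
#' @param proposedId new component id (1-3 characters).
#' @param ccd named list of \linkS4class{ChemComp}.
#' @return list(comp = the new \linkS4class{ChemComp}, ccd = the updated
#'   dictionary).
#' @export
registerComponent <- function(graph, proposedId, ccd) {
  if (proposedId %in% names(ccd))
    .stopf("minidepIdCollision", "component id '%s' already taken", proposedId)
  for (comp in ccd) {
    if (nrow(comp@atoms) == nrow(graph@atoms) &&
        nrow(comp@bonds) == nrow(graph@edges) &&
        length(.subgraphMappings(graph@atoms, graph@edges, comp@atoms,
                                 comp@bonds, maxMaps = 1L)))
      .stopf("minidepDuplicateComponent",
             "graph is isomorphic to existing component %s", comp@compId)
  }
  bonds <- graph@edges
  bonds$order <- rep("single", nrow(bonds))
  xyz <- .xyzMatrix(graph@atoms)
  rownames(xyz) <- graph@atoms$name
  comp <- new("ChemComp", compId = proposedId,
              atoms = data.frame(name = graph@atoms$name,
                                 element = graph@atoms$element,
                                 charge = 0, stringsAsFactors = FALSE),
              bonds = bonds, stereocenters = list(), idealXyz = xyz)
  attr(comp, "needsReview") <- TRUE
  ccd[[proposedId]] <- comp
  list(comp = comp, ccd = ccd)
}

#' Read / write a mini chemical component dictionary
#'
#' The file uses mmCIF-style chem_comp / chem_comp_atom / chem_comp_bond
#' tables plus a minidep_chem_comp_stereo table carrying stereocenter
#' parities (center atom, comma-separated ordered neighbors, parity).
#'
#' @param path CCD file path.
#' @return \code{readCcd}: a named list of \linkS4class{ChemComp}.
#' @export
readCcd <- function(path) {
  block <- readMmcif(path)
  tabs <- block@tables
  cc <- tabs[["chem_comp"]]
  out <- list()
  for (cid in cc$id) {
    at <- tabs[["chem_comp_atom"]]
    at <- at[at$comp_id == cid, , drop = FALSE]
    bd <- tabs[["chem_comp_bond"]]
    bd <- if (is.null(bd)) NULL else bd[bd$comp_id == cid, , drop = FALSE]
    st <- tabs[["minidep_chem_comp_stereo"]]
    st <- if (is.null(st)) NULL else st[st$comp_id == cid, , drop = FALSE]
    atoms <- data.frame(name = at$atom_id, element = at$type_symbol,
                        charge = as.numeric(at$charge), stringsAsFactors = FALSE)
    bonds <- if (is.null(bd) || !nrow(bd))
      data.frame(a = character(0), b = character(0), order = character(0),
                 stringsAsFactors = FALSE)
    else data.frame(a = bd$atom_id_1, b = bd$atom_id_2, order = bd$value_order,
                    stringsAsFactors = FALSE)
    stereo <- list()
    if (!is.null(st) && nrow(st)) for (r in seq_len(nrow(st)))
      stereo[[length(stereo) + 1]] <- list(
        center = st$atom_id[r],
        neighbors = strsplit(st$neighbors[r], ",", fixed = TRUE)[[1]],
        parity = as.numeric(st$parity[r]))
    xyz <- matrix(numeric(0), 0, 3)
    if (all(c("model_Cartn_x_ideal", "model_Cartn_y_ideal",
              "model_Cartn_z_ideal") %in% names(at)) &&
        !any(.isNullValue(at$model_Cartn_x_ideal))) {
      xyz <- cbind(as.numeric(at$model_Cartn_x_ideal),
                   as.numeric(at$model_Cartn_y_ideal),
                   as.numeric(at$model_Cartn_z_ideal))
      rownames(xyz) <- at$atom_id
    }
    out[[cid]] <- new("ChemComp", compId = cid, atoms = atoms, bonds = bonds,
                      stereocenters = stereo, idealXyz = xyz)
  }
  out
}

#' @rdname readCcd
#' @param ccd named list of \linkS4class{ChemComp}.
#' @export
writeCcd <- function(ccd, path = NULL) {
  fmt <- function(v) formatC(v, format = "fg", digits = 12)
  cc <- data.frame(id = vapply(ccd, function(c) c@compId, character(1)),
                   stringsAsFactors = FALSE, row.names = NULL)
  atRows <- list(); bdRows <- list(); stRows <- list()
  for (comp in ccd) {
    hasXyz <- nrow(comp@idealXyz) > 0
    atRows[[length(atRows) + 1]] <- data.frame(
      comp_id = comp@compId, atom_id = comp@atoms$name,
      type_symbol = comp@atoms$element,
      charge = fmt(comp@atoms$charge),
      model_Cartn_x_ideal = if (hasXyz) fmt(comp@idealXyz[, 1]) else "?",
      model_Cartn_y_ideal = if (hasXyz) fmt(comp@idealXyz[, 2]) else "?",
      model_Cartn_z_ideal = if (hasXyz) fmt(comp@idealXyz[, 3]) else "?",
      stringsAsFactors = FALSE)
    if (nrow(comp@bonds))
      bdRows[[length(bdRows) + 1]] <- data.frame(
        comp_id = comp@compId, atom_id_1 = comp@bonds$a,
        atom_id_2 = comp@bonds$b, value_order = comp@bonds$order,
        stringsAsFactors = FALSE)
    for (sc in comp@stereocenters)
      stRows[[length(stRows) + 1]] <- data.frame(
        comp_id = comp@compId, atom_id = sc$center,
        neighbors = paste(sc$neighbors, collapse = ","),
        parity = fmt(sc$parity), stringsAsFactors = FALSE)
  }
  tabs <- list(chem_comp = cc,
               chem_comp_atom = do.call(rbind, atRows))
  if (length(bdRows)) tabs$chem_comp_bond <- do.call(rbind, bdRows)
  if (length(stRows)) tabs$minidep_chem_comp_stereo <- do.call(rbind, stRows)
  writeMmcif(new("DataBlock", blockId = "mini_ccd", tables = tabs), path)
}
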