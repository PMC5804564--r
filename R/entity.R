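# Entity transformation: polymer/non-polymer/water classification, backbone
# link detection, chain split/merge, peptide-reference matching and
# transformation between polymer and non-polymer representations.

# Keep the highest-occupancy alternate conformer per atom name (ties: the
# lexicographically smallest alt id). All geometry uses this view.
.dedupAlt <- function(atoms) {
  if (!nrow(atoms) || all(is.na(atoms$altId))) return(atoms)
  key <- paste(atoms$seqNum, atoms$atomName, sep = "\r")
  ord <- order(key, -atoms$occupancy, atoms$altId, na.last = FALSE)
  atoms <- atoms[ord, , drop = FALSE]
  atoms[!duplicated(paste(atoms$seqNum, atoms$atomName, sep = "\r")), ,
        drop = FALSE]
}

# Ordered residue list for one chain: list(seqNum, compId, atoms).
.residues <- function(chainAtoms) {
  chainAtoms <- .dedupAlt(chainAtoms)
  sq <- sort(unique(chainAtoms$seqNum))
  lapply(sq, function(s) {
    sub <- chainAtoms[chainAtoms$seqNum == s, , drop = FALSE]
    list(seqNum = s, compId = sub$compId[1], atoms = sub)
  })
}

.atomXyz <- function(res, name) {
  k <- match(name, res$atoms$atomName)
  if (is.na(k)) return(NULL)
  as.numeric(res$atoms[k, c("x", "y", "z")])
}

#' Detect standard backbone linkage along a chain
#'
#' Consecutive residues are linked when the peptide C(i)-N(i+1) distance
#' falls in [1.2, 1.8] Angstrom, or the nucleic-acid O3'(i)-P(i+1) distance
#' falls in [1.4, 1.8] Angstrom. Everything else is a break, reported with
#' the measured distance (or reason missing_atom when the backbone atoms
#' are absent). The windows are generous covalent windows, configurable.
#'
#' @param chainAtoms atom records of one chain (data.frame as in
#'   \code{atomRecords}).
#' @param peptideWindow,nucleicWindow inclusive distance windows (Angstrom).
#' @return list(links, breaks, findings): links has columns from, to, type,
#'   distance; breaks has from, to, reason, distance.
#' @export
detectPolymerLinks <- function(chainAtoms,
                               peptideWindow = c(1.2, 1.8),
                               nucleicWindow = c(1.4, 1.8)) {
  rs <- .residues(chainAtoms)
  links <- list(); breaks <- list(); fnd <- list()
  chain <- if (nrow(chainAtoms)) chainAtoms$chain[1] else ""
  if (length(rs) >= 2) for (i in seq_len(length(rs) - 1)) {
    a <- rs[[i]]; b <- rs[[i + 1]]
    cXyz <- .atomXyz(a, "C"); nXyz <- .atomXyz(b, "N")
    o3Xyz <- .atomXyz(a, "O3'"); pXyz <- .atomXyz(b, "P")
    rec <- NULL
    if (!is.null(cXyz) && !is.null(nXyz)) {
      d <- .vnorm(nXyz - cXyz)
      rec <- list(type = "peptide", d = d, win = peptideWindow)
    } else if (!is.null(o3Xyz) && !is.null(pXyz)) {
      d <- .vnorm(pXyz - o3Xyz)
      rec <- list(type = "nucleic", d = d, win = nucleicWindow)
    }
    if (is.null(rec)) {
      breaks <- c(breaks, list(data.frame(
        from = a$seqNum, to = b$seqNum, reason = "missing_atom",
        distance = NA_real_, stringsAsFactors = FALSE)))
      fnd <- c(fnd, list(finding(
        "missing_atom",
        sprintf("backbone atoms missing between %s:%d and %s:%d", chain,
                a$seqNum, chain, b$seqNum),
        locus = sprintf("%s:%d-%d", chain, a$seqNum, b$seqNum))))
    } else if (rec$d >= rec$win[1] && rec$d <= rec$win[2]) {
      links <- c(links, list(data.frame(
        from = a$seqNum, to = b$seqNum, type = rec$type,
        distance = rec$d, stringsAsFactors = FALSE)))
    } else {
      breaks <- c(breaks, list(data.frame(
        from = a$seqNum, to = b$seqNum, reason = "distance",
        distance = rec$d, stringsAsFactors = FALSE)))
      fnd <- c(fnd, list(finding(
        "Polymer backbone linkage",
        sprintf("%s bond %s:%d-%d measures %.2f A (outside [%.2f, %.2f])",
                rec$type, chain, a$seqNum, b$seqNum, rec$d,
                rec$win[1], rec$win[2]),
        locus = sprintf("%s:%d-%d", chain, a$seqNum, b$seqNum))))
    }
  }
  emptyLinks <- data.frame(from = integer(0), to = integer(0),
                           type = character(0), distance = numeric(0),
                           stringsAsFactors = FALSE)
  emptyBreaks <- data.frame(from = integer(0), to = integer(0),
                            reason = character(0), distance = numeric(0),
                            stringsAsFactors = FALSE)
  list(links = if (length(links)) do.call(rbind, links) else emptyLinks,
       breaks = if (length(breaks)) do.call(rbind, breaks) else emptyBreaks,
       findings = .bindFindingsList(fnd))
}

# Classify the residues of one chain into polymer runs / hetero singletons.
# A polymer run is a maximal stretch of >= minPolymerLength residues joined
# by standard backbone links (gaps between runs keep the chain polymeric).
.classifyChain <- function(chainAtoms, minPolymerLength = 2) {
  rs <- .residues(chainAtoms)
  water <- vapply(rs, function(r) r$compId %in% .waterComps, logical(1))
  nonWater <- rs[!water]
  polymerIdx <- integer(0)
  fnd <- emptyFindings()
  if (length(nonWater) >= minPolymerLength) {
    sub <- chainAtoms[!chainAtoms$compId %in% .waterComps, , drop = FALSE]
    det <- detectPolymerLinks(sub)
    fnd <- det$findings
    linked <- rep(FALSE, length(nonWater))
    sq <- vapply(nonWater, function(r) r$seqNum, integer(1))
    runStart <- 1
    for (i in seq_along(nonWater)) {
      isEnd <- i == length(nonWater) ||
        !any(det$links$from == sq[i] & det$links$to == sq[i + 1])
      if (isEnd) {
        if (i - runStart + 1 >= minPolymerLength)
          linked[runStart:i] <- TRUE
        runStart <- i + 1
      }
    }
    polymerIdx <- which(linked)
  }
  list(residues = rs,
       waterSeq = vapply(rs[water], function(r) r$seqNum, integer(1)),
       polymer = nonWater[polymerIdx],
       hetero = nonWater[setdiff(seq_along(nonWater), polymerIdx)],
       findings = fnd)
}

#' Group chains and residues into entities
#'
#' Builds the entity model of a deposition: polymer chains sharing a sample
#' sequence form one polymer entity (multiple instances of one chemically
#' distinct molecule); every non-polymer residue instance is grouped by
#' component id into a non-polymer entity (covalently attached ligands such
#' as glycans stay non-polymer); all waters pool into a single water
#' entity. A polymer chain without a depositor sample sequence raises a
#' missing-mandatory-sequence finding (sequences are a deposition mandate).
#'
#' @param dep a \linkS4class{Deposition}.
#' @param minPolymerLength minimum run of standard-linked residues for a
#'   chain to count as polymeric (default 2; single free amino acids are
#'   non-polymer entities).
#' @return list(deposition, findings): the deposition with its
#'   \code{entityTable} filled (columns entityId, etype, sequence, compId,
#'   instances list-column).
#' @export
buildEntities <- function(dep, minPolymerLength = 2) {
  chains <- unique(dep@atoms$chain)
  fnd <- list()
  polymerKey <- character(0)   # chain -> grouping sequence
  waters <- character(0)
  hetero <- list()             # list of (compId, locus)
  for (ch in chains) {
    cls <- .classifyChain(dep@atoms[dep@atoms$chain == ch, , drop = FALSE],
                          minPolymerLength)
    fnd <- c(fnd, list(cls$findings))
    if (length(cls$polymer)) {
      if (!ch %in% names(dep@sampleSequences)) {
        fnd <- c(fnd, list(finding(
          "missing_sample_sequence",
          sprintf("polymer chain %s has no depositor sample sequence", ch),
          locus = ch)))
        polymerKey[ch] <- paste(.comp2letter(
          vapply(cls$polymer, function(r) r$compId, character(1))),
          collapse = "")
      } else polymerKey[ch] <- dep@sampleSequences[[ch]]
    }
    for (s in cls$waterSeq) waters <- c(waters, sprintf("%s:%d", ch, s))
    for (r in cls$hetero)
      hetero <- c(hetero, list(list(compId = r$compId,
                                    locus = sprintf("%s:%d", ch, r$seqNum))))
  }
  rows <- list(); eid <- 0
  for (key in unique(unname(polymerKey))) {
    eid <- eid + 1
    rows <- c(rows, list(data.frame(
      entityId = eid, etype = "polymer", sequence = key,
      compId = NA_character_, stringsAsFactors = FALSE)))
    rows[[length(rows)]]$instances <- I(list(names(polymerKey)[polymerKey == key]))
  }
  for (cid in unique(vapply(hetero, function(h) h$compId, character(1)))) {
    eid <- eid + 1
    loci <- vapply(hetero[vapply(hetero, function(h) h$compId == cid,
                                 logical(1))],
                   function(h) h$locus, character(1))
    rows <- c(rows, list(data.frame(
      entityId = eid, etype = "non-polymer", sequence = NA_character_,
      compId = cid, stringsAsFactors = FALSE)))
    rows[[length(rows)]]$instances <- I(list(loci))
  }
  if (length(waters)) {
    eid <- eid + 1
    rows <- c(rows, list(data.frame(
      entityId = eid, etype = "water", sequence = NA_character_,
      compId = "HOH", stringsAsFactors = FALSE)))
    rows[[length(rows)]]$instances <- I(list(waters))
  }
  dep@entities <- if (length(rows)) do.call(rbind, rows) else
    data.frame(entityId = integer(0), etype = character(0),
               sequence = character(0), compId = character(0))
  list(deposition = dep, findings = .bindFindingsList(fnd))
}

#' Split or merge polymer chains according to linkage and depositor intent
#'
#' Two depositor chains joined by a standard backbone link merge into one
#' chain (the second renumbered to continue the first, original numbers
#' logged); a chain with an unbridged break splits on depositor
#' confirmation. Residues and atoms are conserved exactly. A merge request
#' without a covalent link is an error requiring correspondence.
#'
#' @param dep a \linkS4class{Deposition}.
#' @param intent list with optional elements \code{merge} (list of
#'   c(chainA, chainB) pairs) and \code{split} (list of
#'   list(chain=, after=, newId=) records).
#' @return list(deposition, findings).
#' @export
splitOrMerge <- function(dep, intent = list()) {
  fnd <- list()
  atoms <- dep@atoms
  for (pair in intent$merge %||% list()) {
    a <- pair[1]; b <- pair[2]
    ra <- .residues(atoms[atoms$chain == a, , drop = FALSE])
    rb <- .residues(atoms[atoms$chain == b, , drop = FALSE])
    if (!length(ra) || !length(rb)) next
    cXyz <- .atomXyz(ra[[length(ra)]], "C"); nXyz <- .atomXyz(rb[[1]], "N")
    d <- if (!is.null(cXyz) && !is.null(nXyz)) .vnorm(nXyz - cXyz) else NA
    if (is.na(d) || d < 1.2 || d > 1.8) {
      fnd <- c(fnd, list(finding(
        "merge_conflict",
        sprintf("merge of %s+%s requested but no backbone link found (C-N %s A)",
                a, b, ifelse(is.na(d), "unmeasurable", sprintf("%.2f", d))),
        locus = paste0(a, "+", b))))
      next
    }
    lastNum <- ra[[length(ra)]]$seqNum
    sel <- atoms$chain == b
    oldNums <- sort(unique(atoms$seqNum[sel]))
    newNums <- lastNum + seq_along(oldNums)
    atoms$seqNum[sel] <- newNums[match(atoms$seqNum[sel], oldNums)]
    atoms$chain[sel] <- a
    fnd <- c(fnd, list(finding(
      "chain_merged",
      sprintf("chain %s merged into %s; residues %d-%d renumbered %d-%d",
              b, a, oldNums[1], oldNums[length(oldNums)], newNums[1],
              newNums[length(newNums)]),
      locus = a)))
  }
  for (sp in intent$split %||% list()) {
    ch <- sp$chain; after <- sp$after
    sub <- atoms[atoms$chain == ch, , drop = FALSE]
    det <- detectPolymerLinks(sub[!sub$compId %in% .waterComps, , drop = FALSE])
    hasBreak <- any(det$breaks$from == after)
    if (!hasBreak) {
      fnd <- c(fnd, list(finding(
        "correspondence_needed",
        sprintf("split of chain %s after residue %d requested but residues are linked",
                ch, after),
        locus = sprintf("%s:%d", ch, after))))
      next
    }
    newId <- sp$newId %||% setdiff(LETTERS, unique(atoms$chain))[1]
    sel <- atoms$chain == ch & atoms$seqNum > after
    atoms$chain[sel] <- newId
    fnd <- c(fnd, list(finding(
      "chain_split",
      sprintf("chain %s split after residue %d; tail renamed %s", ch, after,
              newId),
      locus = sprintf("%s:%d", ch, after))))
  }
  dep@atoms <- atoms
  list(deposition = dep, findings = .bindFindingsList(fnd))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
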