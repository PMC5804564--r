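# Sequence reconciliation: coordinate-derived sequence, reference search,
# controlled-vocabulary discrepancy annotation, chimera segmentation and
# residue-label repair.
#
# Alignments use a simple identity scoring scheme (match +2, mismatch -1,
# gap open -5, gap extend -1; a gap of length L costs 5 + L). Local hits
# are Smith-Waterman; the reconcile alignment is global with free end gaps
# so terminal tags and reference overhangs are not penalized. Positions are
# 1-based and ranges inclusive throughout.

.alignAlphabet <- c(unname(.aa3to1), "X")

.aaSubMatrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      a <- .alignAlphabet
      m <<- matrix(-1, length(a), length(a), dimnames = list(a, a))
      diag(m) <<- 2
    }
    m
  }
})

# Wrapper around Biostrings::pairwiseAlignment returning plain pieces.
.alignPair <- function(pattern, subject, type = "overlap",
                       gapOpening = 5, gapExtension = 1) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pattern), Biostrings::AAString(subject),
    substitutionMatrix = .aaSubMatrix(), gapOpening = gapOpening,
    gapExtension = gapExtension, type = type)
  list(score = Biostrings::score(al),
       pAligned = as.character(Biostrings::alignedPattern(al)),
       sAligned = as.character(Biostrings::alignedSubject(al)),
       pStart = Biostrings::start(Biostrings::pattern(al)),
       pEnd = Biostrings::end(Biostrings::pattern(al)),
       sStart = Biostrings::start(Biostrings::subject(al)),
       sEnd = Biostrings::end(Biostrings::subject(al)))
}

#' Read a reference-sequence database
#'
#' FASTA with the header grammar \code{>accession|taxonomy_id|scientific
#' name}. Nonstandard letters are mapped to X.
#'
#' @param path FASTA file.
#' @return data.frame with columns accession, taxonomyId, scientificName,
#'   sequence.
#' @export
readRefDb <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  hdr <- names(set)
  parts <- strsplit(hdr, "|", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3
  if (any(bad))
    .stopf("minidepParseError", "bad reference header: '%s'",
           hdr[bad][1])
  data.frame(
    accession = vapply(parts, `[`, character(1), 1),
    taxonomyId = as.integer(vapply(parts, `[`, character(1), 2)),
    scientificName = vapply(parts, function(p)
      paste(p[-(1:2)], collapse = "|"), character(1)),
    sequence = gsub(sprintf("[^%s]", paste(.alignAlphabet, collapse = "")),
                    "X", as.character(set)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Derive the coordinate sequence of a polymer chain
#'
#' Translates the modeled residues to one-letter codes placed at their
#' sample positions (residue numbering is sample-position based after
#' curation); unmodeled sample positions become gaps. A modeled residue
#' that disagrees with the sample sequence raises a "Sequence discrepancy"
#' error, and a residue numbered outside the sample raises an error
#' finding (not alignable into the sample).
#'
#' @param chainAtoms atom records of the polymer chain.
#' @param sample the depositor sample sequence (one-letter, with (XXX)
#'   inserts for nonstandard residues).
#' @return list(coordSeq = one-letter string with "-" gaps, findings).
#' @export
deriveCoordSequence <- function(chainAtoms, sample) {
  tokens <- .seqTokens(sample)
  n <- length(tokens)
  coord <- rep("-", n)
  fnd <- list()
  chain <- if (nrow(chainAtoms)) chainAtoms$chain[1] else ""
  for (r in .residues(chainAtoms[!chainAtoms$compId %in% .waterComps, ,
                                 drop = FALSE])) {
    pos <- r$seqNum
    letter <- .comp2letter(r$compId)
    if (pos < 1 || pos > n) {
      fnd <- c(fnd, list(finding(
        "Sequence discrepancy",
        sprintf("residue %s:%d (%s) lies outside the sample sequence (1-%d)",
                chain, pos, r$compId, n),
        locus = sprintf("%s:%d", chain, pos))))
      next
    }
    sampleTok <- tokens[pos]
    sampleLetter <- if (startsWith(sampleTok, "("))
      .comp2letter(gsub("[()]", "", sampleTok)) else sampleTok
    sampleComp <- if (startsWith(sampleTok, "(")) gsub("[()]", "", sampleTok)
                  else .aa1to3[sampleTok]
    coord[pos] <- letter
    agrees <- if (startsWith(sampleTok, "(")) identical(r$compId, sampleComp)
              else identical(letter, sampleLetter)
    if (!agrees)
      fnd <- c(fnd, list(finding(
        "Sequence discrepancy",
        sprintf("coordinates have %s at %s:%d where the sample sequence has %s",
                r$compId, chain, pos, sampleTok),
        locus = sprintf("%s:%d", chain, pos))))
  }
  list(coordSeq = paste(coord, collapse = ""),
       findings = .bindFindingsList(fnd))
}

# Sample sequence as a plain 20+X string for alignment (nonstandard
# residues become X).
.sampleToPlain <- function(sample) {
  toks <- .seqTokens(sample)
  paste(ifelse(startsWith(toks, "("), "X", toks), collapse = "")
}

#' Rank reference-database hits for a sample sequence
#'
#' Smith-Waterman local alignment against every reference; hits are ranked
#' by alignment score with agreement with the declared source taxonomy
#' breaking score ties, then accession. Hits below minScore are dropped.
#'
#' @param sample sample sequence.
#' @param refdb data.frame from \code{\link{readRefDb}}.
#' @param declaredTaxonomy optional declared taxonomy id.
#' @param minScore minimum local alignment score (default 30).
#' @return data.frame of hits: accession, score, taxonomyId, taxMatch,
#'   sampleStart/End, refStart/End (may be empty).
#' @export
searchReferences <- function(sample, refdb, declaredTaxonomy = NULL,
                             minScore = 30) {
  if (!nrow(refdb)) .stopf("minidepArgumentError", "empty reference database")
  plain <- .sampleToPlain(sample)
  rows <- lapply(seq_len(nrow(refdb)), function(k) {
    al <- .alignPair(plain, refdb$sequence[k], type = "local")
    data.frame(accession = refdb$accession[k], score = al$score,
               taxonomyId = refdb$taxonomyId[k],
               taxMatch = !is.null(declaredTaxonomy) &&
                 refdb$taxonomyId[k] == declaredTaxonomy,
               sampleStart = al$pStart, sampleEnd = al$pEnd,
               refStart = al$sStart, refEnd = al$sEnd,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, rows)
  hits <- hits[hits$score >= minScore, , drop = FALSE]
  hits[order(-hits$score, -hits$taxMatch, hits$accession), , drop = FALSE]
}

# Packaged tag motifs: common purification tags and protease sites. The
# distinction between expression tag and cloning artifact is otherwise a
# depositor description, so the motif table is an explicit surrogate.
.tagMotifs <- c(hexahistidine = "HHHHHH", thrombin = "LVPRGS",
                tev = "ENLYFQ", flag = "DYKDDDDK", strep = "WSHPQFEK")

.parseRangeDecl <- function(s) {
  m <- regmatches(s, regexec("^(\\d+)-(\\d+)$", s))[[1]]
  if (length(m) != 3) return(NULL)
  c(as.integer(m[2]), as.integer(m[3]))
}

.parseMutationDecl <- function(s) {
  m <- regmatches(s, regexec("^([A-Z])(\\d+)([A-Z])$", s))[[1]]
  if (length(m) != 4) return(NULL)
  list(from = m[2], pos = as.integer(m[3]), to = m[4])
}

#' Reconcile sample, coordinate and reference sequences
#'
#' Aligns the sample to the reference (global, free end gaps) and
#' classifies every discrepancy with the controlled vocabulary, applying
#' the rules in order: (1) a terminal sample-only span that matches a
#' packaged tag motif or is depositor-declared is an expression tag,
#' otherwise a cloning artifact; (2) an internal sample-only span is an
#' insertion (a linker when declared); (3) a reference-only span is a
#' deletion; (4) a single-column conflict is a mutation when
#' depositor-declared engineered, a variant when the reference records it,
#' otherwise a conflict raised for correspondence; (5) sample positions
#' absent from the coordinates are unmodeled. Every non-identical
#' alignment column receives exactly one class.
#'
#' @param sample sample sequence.
#' @param coordSeq coordinate-derived sequence from
#'   \code{\link{deriveCoordSequence}} (or NULL to skip rule 5).
#' @param ref one row of the reference database (list or 1-row
#'   data.frame), optionally carrying a \code{variants} attribute
#'   (data.frame pos, from, to).
#' @param declarations depositor declarations (named list; recognized
#'   kinds: mutation "Y64W", tag_range "1-9", linker_range "10-14").
#' @return list(annotations = data.frame(start, end, class, evidence),
#'   findings).
#' @export
reconcileSequences <- function(sample, coordSeq = NULL, ref,
                               declarations = list()) {
  plain <- .sampleToPlain(sample)
  refSeq <- if (is.data.frame(ref)) ref$sequence[1] else ref$sequence
  acc <- if (is.data.frame(ref)) ref$accession[1] else ref$accession
  variants <- attr(ref, "variants")
  al <- .alignPair(plain, refSeq, type = "overlap")
  n <- nchar(plain)
  ann <- list(); fnd <- list()
  addAnn <- function(start, end, class, evidence) {
    ann[[length(ann) + 1]] <<- data.frame(
      start = start, end = end, class = class, evidence = evidence,
      stringsAsFactors = FALSE)
  }
  declaredTags <- lapply(declarations$tag_range %||% character(0),
                         .parseRangeDecl)
  declaredLinkers <- lapply(declarations$linker_range %||% character(0),
                            .parseRangeDecl)
  declaredMuts <- Filter(Negate(is.null),
                         lapply(declarations$mutation %||% character(0),
                                .parseMutationDecl))
  coveredByDecl <- function(ranges, lo, hi) {
    any(vapply(ranges, function(r) !is.null(r) && r[1] <= lo && r[2] >= hi,
               logical(1)))
  }
  classifyTerminal <- function(lo, hi) {
    span <- substr(plain, lo, hi)
    tagged <- coveredByDecl(declaredTags, lo, hi) ||
      any(vapply(.tagMotifs, function(m) grepl(m, span, fixed = TRUE),
                 logical(1)))
    addAnn(lo, hi, if (tagged) "expression tag" else "cloning artifact",
           sprintf("terminal sample-only span vs %s", acc))
  }
  # terminal sample overhangs (free end gaps)
  if (al$pStart > 1) classifyTerminal(1, al$pStart - 1)
  if (al$pEnd < n) classifyTerminal(al$pEnd + 1, n)
  # terminal reference overhangs -> deletions anchored at the sample edge
  if (al$sStart > 1)
    addAnn(max(al$pStart - 1, 0), max(al$pStart - 1, 0), "deletion",
           sprintf("reference %s residues 1-%d absent from sample", acc,
                   al$sStart - 1))
  if (al$sEnd < nchar(refSeq))
    addAnn(al$pEnd, al$pEnd, "deletion",
           sprintf("reference %s residues %d-%d absent from sample", acc,
                   al$sEnd + 1, nchar(refSeq)))
  # walk the aligned columns
  pChars <- strsplit(al$pAligned, "")[[1]]
  sChars <- strsplit(al$sAligned, "")[[1]]
  pPos <- al$pStart - 1; sPos <- al$sStart - 1
  i <- 1
  while (i <= length(pChars)) {
    if (sChars[i] == "-") {           # sample-only span (insertion)
      lo <- pPos + 1
      while (i <= length(pChars) && sChars[i] == "-") {
        pPos <- pPos + 1; i <- i + 1
      }
      hi <- pPos
      addAnn(lo, hi,
             if (coveredByDecl(declaredLinkers, lo, hi)) "linker"
             else "insertion",
             sprintf("sample-only span vs %s", acc))
    } else if (pChars[i] == "-") {    # reference-only span (deletion)
      refLo <- sPos + 1
      while (i <= length(pChars) && pChars[i] == "-") {
        sPos <- sPos + 1; i <- i + 1
      }
      addAnn(pPos, pPos, "deletion",
             sprintf("reference %s residues %d-%d absent from sample", acc,
                     refLo, sPos))
    } else {
      pPos <- pPos + 1; sPos <- sPos + 1
      if (pChars[i] != sChars[i]) {
        declared <- any(vapply(declaredMuts, function(m)
          m$pos == pPos && m$to == pChars[i], logical(1)))
        isVariant <- !is.null(variants) &&
          any(variants$pos == sPos & variants$to == pChars[i])
        cls <- if (declared) "mutation" else if (isVariant) "variant"
               else "conflict"
        addAnn(pPos, pPos, cls,
               sprintf("%s%d in %s vs %s in sample", sChars[i], sPos, acc,
                       pChars[i]))
        if (cls == "conflict")
          fnd <- c(fnd, list(finding(
            "correspondence_needed",
            sprintf("undeclared %s->%s conflict at sample position %d vs %s",
                    sChars[i], pChars[i], pPos, acc),
            locus = as.character(pPos))))
      }
      i <- i + 1
    }
  }
  # unmodeled sample regions
  if (!is.null(coordSeq)) {
    cc <- strsplit(coordSeq, "")[[1]]
    k <- 1
    while (k <= length(cc)) {
      if (cc[k] == "-") {
        lo <- k
        while (k <= length(cc) && cc[k] == "-") k <- k + 1
        addAnn(lo, k - 1, "unmodeled", "absent from the atomic coordinates")
      } else k <- k + 1
    }
  }
  annDf <- if (length(ann)) do.call(rbind, ann) else
    data.frame(start = integer(0), end = integer(0), class = character(0),
               evidence = character(0), stringsAsFactors = FALSE)
  annDf <- annDf[order(annDf$start, annDf$end), , drop = FALSE]
  rownames(annDf) <- NULL
  list(annotations = annDf, findings = .bindFindingsList(fnd))
}

# Recursively collect local hits of sample[lo..hi] against one reference.
.collectLocalHits <- function(plain, refRow, lo, hi, minScore, minLen) {
  if (hi - lo + 1 < minLen) return(NULL)
  seg <- substr(plain, lo, hi)
  al <- .alignPair(seg, refRow$sequence, type = "local")
  if (al$score < minScore) return(NULL)
  hit <- data.frame(
    start = lo + al$pStart - 1, end = lo + al$pEnd - 1,
    accession = refRow$accession, refStart = al$sStart, refEnd = al$sEnd,
    pAligned = al$pAligned, sAligned = al$sAligned,
    stringsAsFactors = FALSE)
  rbind(hit,
        .collectLocalHits(plain, refRow, lo, hit$start - 1, minScore, minLen),
        .collectLocalHits(plain, refRow, hit$end + 1, hi, minScore, minLen))
}

# Decompose one local hit into ungapped candidate blocks (constant
# sample-to-reference offset within each block).
.hitBlocks <- function(hit) {
  pC <- strsplit(hit$pAligned, "")[[1]]
  sC <- strsplit(hit$sAligned, "")[[1]]
  p <- hit$start - 1; s <- hit$refStart - 1
  blocks <- list(); curStart <- NULL; curRef <- NULL
  flush <- function(endP) {
    if (!is.null(curStart))
      blocks[[length(blocks) + 1]] <<- data.frame(
        accession = hit$accession, start = curStart, end = endP,
        refStart = curRef, stringsAsFactors = FALSE)
    curStart <<- NULL
  }
  for (k in seq_along(pC)) {
    if (pC[k] != "-" && sC[k] != "-") {
      p <- p + 1; s <- s + 1
      if (is.null(curStart)) { curStart <- p; curRef <- s }
    } else {
      flush(p)
      if (pC[k] != "-") p <- p + 1
      if (sC[k] != "-") s <- s + 1
    }
  }
  flush(p)
  blocks
}

#' Segment a (possibly chimeric) sample over the reference database
#'
#' Local hits of the sample against every reference are collected
#' (recursively, so one reference can contribute several hits) and
#' decomposed into ungapped candidate blocks. A per-position dynamic
#' program then assigns every sample position to one candidate (or to
#' "unassigned"), scoring +2 per matching position and -1 per mismatching
#' position, charging \code{kappa} for switching between candidates of
#' different references and a small gap penalty for switches within one
#' reference or into/out of unassigned. Consecutive positions assigned to
#' one reference form the segments; unassigned runs of at most
#' \code{absorb} residues are merged into the longer flanking segment,
#' longer runs are reported with a warning. The construct is chimeric when
#' the map uses at least two distinct accessions.
#'
#' @param sample sample sequence.
#' @param refdb reference database data.frame.
#' @param kappa reference switch penalty (default 20; Inf forbids
#'   switches, collapsing to the best single-reference segmentation).
#' @param minScore minimum local hit score.
#' @param minLen minimum span length to search.
#' @param absorb maximum unassigned span absorbed into a flank.
#' @param gapPenalty cost of switching candidates within one reference or
#'   into/out of the unassigned state.
#' @return list(segments = data.frame(start, end, accession, refStart,
#'   refEnd), chimeric, findings).
#' @export
segmentChimera <- function(sample, refdb, kappa = 20, minScore = 30,
                           minLen = 8, absorb = 3, gapPenalty = 5) {
  plain <- .sampleToPlain(sample)
  n <- nchar(plain)
  sChars <- strsplit(plain, "")[[1]]
  hits <- do.call(rbind, lapply(seq_len(nrow(refdb)), function(k)
    .collectLocalHits(plain, refdb[k, ], 1, n, minScore, minLen)))
  fnd <- list()
  unassignedResult <- function() {
    list(segments = data.frame(
      start = 1L, end = n, accession = NA_character_,
      refStart = NA_integer_, refEnd = NA_integer_,
      stringsAsFactors = FALSE),
      chimeric = FALSE,
      findings = finding("unassigned_segment",
                         "no reference hit found; sample left unassigned"))
  }
  if (is.null(hits) || !nrow(hits)) return(unassignedResult())
  cand <- do.call(rbind, unlist(lapply(seq_len(nrow(hits)), function(k)
    .hitBlocks(hits[k, ])), recursive = FALSE))
  if (is.null(cand) || !nrow(cand)) return(unassignedResult())
  cand <- cand[order(cand$accession, cand$start, cand$refStart), ,
               drop = FALSE]
  rownames(cand) <- NULL
  refSeq <- stats::setNames(refdb$sequence, refdb$accession)
  m <- nrow(cand)
  accs <- unique(cand$accession)
  # states: the m candidates, one context-carrying unassigned state per
  # accession (so a cross-accession switch pays kappa even when it is
  # bridged by an unassigned run), and one initial unassigned state
  nStates <- m + length(accs) + 1
  # emission score of candidate c at sample position i (NA when the
  # position lies outside the candidate's span); unassigned states emit 0
  emit <- matrix(NA_real_, nStates, n)
  emit[(m + 1):nStates, ] <- 0
  for (c0 in seq_len(m)) {
    span <- cand$start[c0]:cand$end[c0]
    refPos <- cand$refStart[c0] + span - cand$start[c0]
    refCh <- strsplit(substr(refSeq[[cand$accession[c0]]],
                             refPos[1], refPos[length(refPos)]), "")[[1]]
    emit[c0, span] <- ifelse(sChars[span] == refCh, 2, -1)
  }
  emit[(m + 1):(m + length(accs)), 1] <- NA   # no context at position 1
  accOf <- c(cand$accession, accs, NA_character_)
  isCand <- c(rep(TRUE, m), rep(FALSE, length(accs) + 1))
  trans <- function(s1, s2) {
    if (s1 == s2) return(0)
    a1 <- accOf[s1]; a2 <- accOf[s2]
    if (!isCand[s1] && !isCand[s2]) return(Inf)   # context never mutates idle
    if (is.na(a1)) return(if (isCand[s2]) gapPenalty else Inf)
    if (is.na(a2)) return(Inf)     # the initial unassigned state is entry-only
    if (a1 == a2) return(gapPenalty)
    # accessions differ: entering a candidate costs the switch penalty;
    # entering an unassigned state with the wrong context is impossible
    if (isCand[s2]) kappa else Inf
  }
  dp <- matrix(-Inf, nStates, n); from <- matrix(0L, nStates, n)
  dp[, 1] <- emit[, 1]
  for (i in 2:max(n, 2)) {
    if (n < 2) break
    for (s2 in seq_len(nStates)) {
      if (is.na(emit[s2, i])) next
      bestV <- -Inf; bestS <- 0L
      for (s1 in seq_len(nStates)) {
        if (!is.finite(dp[s1, i - 1])) next
        v <- dp[s1, i - 1] - trans(s1, s2)
        if (v > bestV) { bestV <- v; bestS <- s1 }
      }
      dp[s2, i] <- bestV + emit[s2, i]
      from[s2, i] <- bestS
    }
  }
  states <- integer(n)
  states[n] <- which.max(dp[, n])
  if (n > 1) for (i in (n - 1):1) states[i] <- from[states[i + 1], i + 1]
  # compress the state path into segments
  segs <- list()
  runStart <- 1L
  for (i in seq_len(n)) {
    if (i == n || states[i + 1] != states[i]) {
      s0 <- states[runStart]
      segs[[length(segs) + 1]] <- data.frame(
        start = runStart, end = i,
        accession = if (s0 <= m) accOf[s0] else NA_character_,
        refStart = if (s0 <= m)
          cand$refStart[s0] + runStart - cand$start[s0] else NA_integer_,
        refEnd = if (s0 <= m)
          cand$refStart[s0] + i - cand$start[s0] else NA_integer_,
        stringsAsFactors = FALSE)
      runStart <- i + 1L
    }
  }
  segments <- do.call(rbind, segs)
  # merge adjacent runs of the same accession (different candidates)
  mergeSameAcc <- function(segments) {
    k <- 2
    while (k <= nrow(segments)) {
      if (!is.na(segments$accession[k]) &&
          identical(segments$accession[k], segments$accession[k - 1])) {
        segments$end[k - 1] <- segments$end[k]
        segments$refEnd[k - 1] <- segments$refEnd[k]
        segments <- segments[-k, , drop = FALSE]
      } else k <- k + 1
    }
    segments
  }
  segments <- mergeSameAcc(segments)
  # absorb short unassigned runs into the longer flank
  k <- 1
  while (k <= nrow(segments)) {
    if (is.na(segments$accession[k]) &&
        segments$end[k] - segments$start[k] + 1 <= absorb &&
        nrow(segments) > 1) {
      lenL <- if (k > 1) segments$end[k - 1] - segments$start[k - 1] + 1 else -1
      lenR <- if (k < nrow(segments))
        segments$end[k + 1] - segments$start[k + 1] + 1 else -1
      if (lenL >= lenR) {
        segments$end[k - 1] <- segments$end[k]
      } else {
        segments$start[k + 1] <- segments$start[k]
      }
      segments <- segments[-k, , drop = FALSE]
    } else k <- k + 1
  }
  segments <- mergeSameAcc(segments)
  rownames(segments) <- NULL
  for (k in which(is.na(segments$accession)))
    fnd <- c(fnd, list(finding(
      "unassigned_segment",
      sprintf("sample residues %d-%d match no reference",
              segments$start[k], segments$end[k]))))
  list(segments = segments,
       chimeric = length(unique(stats::na.omit(segments$accession))) >= 2,
       findings = .bindFindingsList(fnd))
}

#' Repair residue labels against the sample sequence
#'
#' Residues modeled as alanine or glycine, or with incomplete sidechains,
#' at positions where the sample sequence says otherwise are relabeled to
#' the sample residue (atoms and coordinates untouched). A residue with a
#' complete sidechain that contradicts the sample is never auto-relabeled:
#' it is raised as a "Sequence discrepancy" for correspondence.
#'
#' @param chainAtoms atom records of the polymer chain.
#' @param sample the depositor sample sequence.
#' @return list(atoms = updated records, edits = data.frame(chain, seqNum,
#'   old, new), findings).
#' @export
repairResidueLabels <- function(chainAtoms, sample) {
  tokens <- .seqTokens(sample)
  edits <- list(); fnd <- list()
  atoms <- chainAtoms
  chain <- if (nrow(atoms)) atoms$chain[1] else ""
  for (r in .residues(atoms[!atoms$compId %in% .waterComps, , drop = FALSE])) {
    pos <- r$seqNum
    if (pos < 1 || pos > length(tokens)) next
    tok <- tokens[pos]
    targetComp <- if (startsWith(tok, "(")) gsub("[()]", "", tok)
                  else unname(.aa1to3[tok])
    if (is.na(targetComp) || identical(r$compId, targetComp)) next
    expected <- .sidechainAtoms[[r$compId]]
    complete <- !is.null(expected) &&
      all(expected %in% r$atoms$atomName)
    if (r$compId %in% c("ALA", "GLY") || !complete) {
      sel <- atoms$chain == chain & atoms$seqNum == pos
      atoms$compId[sel] <- targetComp
      edits[[length(edits) + 1]] <- data.frame(
        chain = chain, seqNum = pos, old = r$compId, new = targetComp,
        stringsAsFactors = FALSE)
      fnd <- c(fnd, list(finding(
        "relabelled_residue",
        sprintf("%s:%d relabeled %s -> %s to match the sample sequence",
                chain, pos, r$compId, targetComp),
        locus = sprintf("%s:%d", chain, pos))))
    } else {
      fnd <- c(fnd, list(finding(
        "Sequence discrepancy",
        sprintf("%s:%d modeled as complete %s where sample says %s",
                chain, pos, r$compId, targetComp),
        locus = sprintf("%s:%d", chain, pos))))
    }
  }
  list(atoms = atoms,
       edits = if (length(edits)) do.call(rbind, edits) else
         data.frame(chain = character(0), seqNum = integer(0),
                    old = character(0), new = character(0)),
       findings = .bindFindingsList(fnd))
}
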