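# Independent oracles for the property suites. These deliberately share no
# code with the package implementations: the subgraph oracle is a plain
# exhaustive enumerator, the alignment oracle is a textbook Gotoh dynamic
# program, and the image-search oracle is a direct triple loop over
# symmetry operators and the 27 neighbouring unit cells.

# ---- brute-force element-labelled subgraph monomorphism ---------------

# Every injective assignment of pattern atoms to target atoms preserving
# element labels and carrying every pattern edge onto a target edge.
oracleSubgraphMaps <- function(pAtoms, pEdges, tAtoms, tEdges) {
  np <- nrow(pAtoms)
  if (np == 0 || np > nrow(tAtoms)) return(list())
  pName <- pAtoms$name
  tName <- tAtoms$name
  pEl <- toupper(pAtoms$element)
  tEl <- toupper(tAtoms$element)
  edgeKey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  tEdgeSet <- if (nrow(tEdges)) edgeKey(tEdges$a, tEdges$b) else character(0)
  maps <- list()
  assign <- character(np)
  recurse <- function(depth, used) {
    if (depth > np) {
      ok <- TRUE
      if (nrow(pEdges)) {
        m <- stats::setNames(assign, pName)
        ok <- all(edgeKey(m[pEdges$a], m[pEdges$b]) %in% tEdgeSet)
      }
      if (ok) maps[[length(maps) + 1]] <<- stats::setNames(assign, pName)
      return(invisible())
    }
    for (k in seq_along(tName)) {
      if (used[k] || tEl[k] != pEl[depth]) next
      assign[depth] <<- tName[k]
      used[k] <- TRUE
      recurse(depth + 1, used)
      used[k] <- FALSE
    }
  }
  recurse(1, logical(length(tName)))
  maps
}

# canonical sorted-key representation so mapping SETS can be compared
canonMapKeys <- function(maps) {
  sort(vapply(maps, function(m) {
    m <- m[sort(names(m))]
    paste(names(m), m, sep = "=", collapse = ";")
  }, character(1)))
}

# ---- textbook Gotoh affine-gap aligner (score only) -------------------

# match +2, mismatch -1, a gap of length L costs 5 + L (open 6, extend 1).
# type "local" is Smith-Waterman; type "overlap" is global with free end
# gaps on both sequences.
oracleAlignScore <- function(pattern, subject, type = c("overlap", "local")) {
  type <- match.arg(type)
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  n <- length(p); m <- length(s)
  open <- 6; ext <- 1
  sub <- function(a, b) if (a == b) 2 else -1
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)   # gap in pattern (consumes subject)
  F <- matrix(NEG, n + 1, m + 1)   # gap in subject (consumes pattern)
  if (type == "local") {
    best <- 0
    for (i in seq_len(n)) for (j in seq_len(m)) {
      E[i + 1, j + 1] <- max(H[i + 1, j] - open, E[i + 1, j] - ext)
      F[i + 1, j + 1] <- max(H[i, j + 1] - open, F[i, j + 1] - ext)
      H[i + 1, j + 1] <- max(0, H[i, j] + sub(p[i], s[j]),
                             E[i + 1, j + 1], F[i + 1, j + 1])
      best <- max(best, H[i + 1, j + 1])
    }
    return(best)
  }
  # overlap: leading end gaps free (H first row/col 0), trailing end gaps
  # free (maximum over the last row and column).
  for (i in seq_len(n)) for (j in seq_len(m)) {
    E[i + 1, j + 1] <- max(H[i + 1, j] - open, E[i + 1, j] - ext)
    F[i + 1, j + 1] <- max(H[i, j + 1] - open, F[i, j + 1] - ext)
    H[i + 1, j + 1] <- max(H[i, j] + sub(p[i], s[j]),
                           E[i + 1, j + 1], F[i + 1, j + 1])
  }
  max(H[n + 1, ], H[, m + 1])
}

# ---- brute-force crystallographic image search ------------------------

# Minimum distance from point p to the polymer over every symmetry image
# in the 27 neighbouring cells, plus the argmin image position.
oracleImageMin <- function(p, polyXyz, M, Minv, ops) {
  pf <- as.numeric(Minv %*% p)
  shifts <- expand.grid(a = -1:1, b = -1:1, c = -1:1)
  best <- list(d = Inf, img = NULL)
  for (op in ops) {
    base <- as.numeric(op$R %*% pf + op$t)
    for (k in seq_len(nrow(shifts))) {
      img <- as.numeric(M %*% (base + as.numeric(shifts[k, ])))
      dx <- polyXyz[, 1] - img[1]
      dy <- polyXyz[, 2] - img[2]
      dz <- polyXyz[, 3] - img[3]
      d <- sqrt(min(dx * dx + dy * dy + dz * dz))
      if (d < best$d - 1e-9) best <- list(d = d, img = img)
    }
  }
  best
}

# ---- random-sequence helpers ------------------------------------------

aaLetters <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

randomProtein <- function(n) paste(sample(aaLetters, n, replace = TRUE),
                                   collapse = "")

# Chimera plant with identifiable boundaries: donor block B[40:69] replaces
# sample positions 80:109 of a 200-residue host A. The four boundary-
# adjacent positions are forced to differ across the switch (see the
# decisions ledger: with fully random content two segmentations are exactly
# co-optimal whenever a boundary-adjacent residue coincides by chance, so
# boundary recovery is only well-posed for identifiable plants).
makeChimeraCase <- function(seed) {
  set.seed(seed)
  repeat {
    a <- strsplit(randomProtein(200), "")[[1]]
    b <- strsplit(randomProtein(120), "")[[1]]
    if (a[80] != b[40] && a[109] != b[69] &&
        a[79] != b[39] && a[110] != b[70]) break
  }
  sample <- a
  sample[80:109] <- b[40:69]
  list(
    refdb = data.frame(
      accession = c("HOSTAA", "DONORB"),
      taxonomyId = c(9606L, 562L),
      scientificName = c("Homo sapiens", "Escherichia coli"),
      sequence = c(paste(a, collapse = ""), paste(b, collapse = "")),
      stringsAsFactors = FALSE),
    sample = paste(sample, collapse = ""))
}
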