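# Ligand processor: graph perception, CCD search, atom-name
# standardization, chirality, registration.

miniCcd <- makeMiniCcd()

instanceAtoms <- function(comp, prefix = "Q") {
  data.frame(chain = "L", seqNum = 1L, compId = comp@compId,
             atomName = paste0(prefix, seq_len(nrow(comp@atoms))),
             element = comp@atoms$element,
             x = comp@idealXyz[, 1], y = comp@idealXyz[, 2],
             z = comp@idealXyz[, 3], occupancy = 1, bFactor = 10,
             altId = NA_character_, stringsAsFactors = FALSE)
}

test_that("perceiveGraph recovers the component bond graph", {
  mnl <- miniCcd[["MNL"]]
  g <- perceiveGraph(instanceAtoms(mnl))
  expect_identical(nrow(g@atoms), nrow(mnl@atoms))
  expect_identical(nrow(g@edges), nrow(mnl@bonds))
})

test_that("searchCcd identifies an exact instance with score 1", {
  mnl <- miniCcd[["MNL"]]
  hits <- searchCcd(perceiveGraph(instanceAtoms(mnl)), miniCcd)
  expect_gt(length(hits), 0)
  expect_identical(compId(hits[[1]]), "MNL")
  expect_equal(matchScore(hits[[1]]), 1)
  ren <- standardizeAtoms(perceiveGraph(instanceAtoms(mnl)), hits[[1]])
  expect_identical(sort(unname(ren)), sort(mnl@atoms$name))
})

test_that("a partially modeled ligand scores below 1 and names the gap", {
  nag <- miniCcd[["NAG"]]
  atoms <- instanceAtoms(nag, prefix = "")
  atoms$atomName <- nag@atoms$name
  partial <- atoms[atoms$atomName != "O6", , drop = FALSE]
  hits <- searchCcd(perceiveGraph(partial), miniCcd)
  expect_identical(compId(hits[[1]]), "NAG")
  expect_lt(matchScore(hits[[1]]), 1)
  expect_identical(hits[[1]]@unmatchedComponentAtoms, "O6")
  expect_error(standardizeAtoms(perceiveGraph(partial), hits[[1]]),
               class = "minidepMatchError")
})

test_that("checkChirality flags a mirrored instance and passes the true one", {
  mnl <- miniCcd[["MNL"]]
  atoms <- instanceAtoms(mnl)
  hit <- searchCcd(perceiveGraph(atoms), miniCcd)[[1]]
  expect_identical(nrow(checkChirality(atoms, mnl, hit@mapping)), 0L)
  flipped <- atoms
  flipped$z <- -flipped$z
  hit2 <- searchCcd(perceiveGraph(flipped), miniCcd)[[1]]
  f <- checkChirality(flipped, mnl, hit2@mapping)
  expect_true(any(f$code == "Chirality error"))
})

test_that("registerComponent mints new ids and refuses duplicates", {
  mnl <- miniCcd[["MNL"]]
  g <- perceiveGraph(instanceAtoms(mnl))
  expect_error(registerComponent(g, "MNL", miniCcd),
               class = "minidepIdCollision")
  expect_error(registerComponent(g, "ZZ1", miniCcd),
               class = "minidepDuplicateComponent")
  # a genuinely new graph registers under the proposed id
  novel <- g
  novel@atoms$element[novel@atoms$element == "N"] <- "P"
  reg <- registerComponent(novel, "ZZ1", miniCcd)
  expect_true("ZZ1" %in% names(reg$ccd))
  expect_identical(compId(reg$comp), "ZZ1")
})

test_that("subgraph matcher agrees with the brute-force enumerator", {
  # all fixture component graphs with at most 8 atoms, as pattern and
  # target in every ordered pair (includes the self pairs = automorphisms)
  sm <- getFromNamespace(".subgraphMappings", "minidep")
  small <- Filter(function(c) nrow(c@atoms) <= 8, miniCcd)
  expect_gte(length(small), 5)
  for (p in small) for (t in small) {
    got <- canonMapKeys(sm(p@atoms, p@bonds, t@atoms, t@bonds))
    want <- canonMapKeys(oracleSubgraphMaps(p@atoms, p@bonds,
                                            t@atoms, t@bonds))
    expect_identical(got, want,
                     info = sprintf("%s -> %s", p@compId, t@compId))
  }
  # and on perceived instance graphs of the small components
  for (p in small) {
    if (p@compId == "HOH") next
    g <- perceiveGraph(instanceAtoms(p))
    for (t in small) {
      got <- canonMapKeys(sm(g@atoms, g@edges, t@atoms, t@bonds))
      want <- canonMapKeys(oracleSubgraphMaps(g@atoms, g@edges,
                                              t@atoms, t@bonds))
      expect_identical(got, want,
                       info = sprintf("instance %s -> %s", p@compId,
                                      t@compId))
    }
  }
})
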