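# Entity builder: chain classification, backbone-link detection,
# split/merge and peptide reference matching.

baseFixture <- makeDeposition(character(0), seed = 2)

test_that("buildEntities groups the base fixture into three entities", {
  res <- buildEntities(baseFixture$deposition)
  ent <- res$deposition@entities
  expect_identical(nrow(ent), 3L)
  expect_identical(ent$etype, c("polymer", "non-polymer", "water"))
  expect_identical(ent$compId[2], "MNL")
  expect_identical(ent$instances[[1]], "A")
  expect_identical(length(ent$instances[[3]]), 5L)
  expect_identical(ent$sequence[1],
                   baseFixture$deposition@sampleSequences[["A"]])
  expect_identical(nrow(res$findings), 0L)
})

test_that("detectPolymerLinks sees every peptide bond of the base chain", {
  atoms <- baseFixture$deposition@atoms
  chainA <- atoms[atoms$chain == "A" & atoms$compId != "HOH" &
                    atoms$compId != "MNL", , drop = FALSE]
  det <- detectPolymerLinks(chainA)
  expect_identical(nrow(det$links), 29L)   # 30 residues, 29 bonds
  expect_identical(nrow(det$breaks), 0L)
  expect_identical(nrow(det$findings), 0L)
})

test_that("a broken backbone yields a linkage finding and a break record", {
  fx <- makeDeposition("Polymer backbone linkage", seed = 2)
  atoms <- fx$deposition@atoms
  chainA <- atoms[atoms$chain == "A" & !atoms$compId %in% c("HOH", "MNL"), ,
                  drop = FALSE]
  det <- detectPolymerLinks(chainA)
  expect_identical(nrow(det$breaks), 1L)
  expect_true(any(det$findings$code == "Polymer backbone linkage"))
})

test_that("splitOrMerge splits at a real break and refuses a fake merge", {
  fx <- makeDeposition("Polymer backbone linkage", seed = 2)
  dep <- fx$deposition
  atoms <- dep@atoms
  chainA <- atoms[atoms$chain == "A" & !atoms$compId %in% c("HOH", "MNL"), ,
                  drop = FALSE]
  det <- detectPolymerLinks(chainA)
  after <- det$breaks$from[1]
  res <- splitOrMerge(dep, list(split = list(list(chain = "A",
                                                  after = after,
                                                  newId = "B"))))
  expect_true(any(res$findings$code == "chain_split"))
  expect_true("B" %in% res$deposition@atoms$chain)
  # splitting then merging the same boundary restores one chain
  res2 <- splitOrMerge(res$deposition, list(merge = list(c("A", "B"))))
  # the break means there is no C-N link, so the merge must be refused
  expect_true(any(res2$findings$code == "merge_conflict"))
  # a split where residues are linked is refused on the clean base
  res3 <- splitOrMerge(baseFixture$deposition,
                       list(split = list(list(chain = "A", after = 15))))
  expect_true(any(res3$findings$code == "correspondence_needed"))
  expect_identical(res3$deposition@atoms, baseFixture$deposition@atoms)
})

test_that("the TPA tripeptide matches the PRD entry in both forms", {
  ccd <- makeMiniCcd()
  prd <- makePrdDb()
  tpa <- ccd[["TPA"]]
  atoms <- data.frame(chain = "X", seqNum = 1L, compId = "TPA",
                      atomName = tpa@atoms$name,
                      element = tpa@atoms$element,
                      x = tpa@idealXyz[, 1], y = tpa@idealXyz[, 2],
                      z = tpa@idealXyz[, 3], occupancy = 1, bFactor = 10,
                      altId = NA_character_, stringsAsFactors = FALSE)
  mol <- asMolecule(atoms, form = "non-polymer")
  expect_identical(matchPrd(mol, prd, ccd = ccd), "PRD1")
  poly <- transformRepresentation(mol, "to_polymer", ccd = ccd)
  expect_identical(poly$form, "polymer")
  expect_identical(matchPrd(poly, prd, ccd = ccd), "PRD1")
  # round trip conserves the atom count
  back <- transformRepresentation(poly, "to_non_polymer", ccd = ccd)
  expect_identical(nrow(back$atoms), nrow(mol$atoms))
})
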