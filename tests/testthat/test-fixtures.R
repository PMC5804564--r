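# Fixture factory: plan vocabulary, determinism, manifest soundness, the
# defect-free base, and the packaged reference/CCD artefacts.

test_that("the plan vocabulary is fixed and invalid plans are refused", {
  codes <- defectPlanCodes()
  expect_identical(anyDuplicated(codes), 0L)
  expect_true(all(c("Atomic clashes", "Chirality error", "tag_and_mutation",
                    "chimera_swap") %in% codes))
  expect_error(makeDeposition("not_a_defect", seed = 1),
               class = "minidepPlanError")
  expect_error(makeDeposition(c("Zero B-factor", "Zero B-factor"), seed = 1),
               class = "minidepPlanError")
})

test_that("the defect-free base curates to zero findings end to end", {
  fx <- makeDeposition(character(0), seed = 9)
  res <- curateDeposition(fx$deposition, refdb = makeRefDb(seed = 9))
  expect_identical(nrow(res$findings), 0L)
  expect_identical(res$report@status, "ok")
  expect_true(all(stageStatus(res$workflow) == "complete"))
  expect_identical(nrow(fx$manifest), 0L)
})

test_that("every single-defect manifest names its plan and locus", {
  for (code in defectPlanCodes()) {
    fx <- makeDeposition(code, seed = 3)
    expect_identical(nrow(fx$manifest), 1L)
    expect_identical(fx$manifest$plan, code)
    expect_false(is.na(fx$manifest$locus))
  }
})

test_that("the reference database round-trips through FASTA", {
  tmp <- tempfile(fileext = ".fasta")
  on.exit(unlink(tmp))
  db <- makeRefDb(seed = 5, path = tmp)
  back <- readRefDb(tmp)
  expect_identical(back$accession, db$accession)
  expect_identical(back$taxonomyId, db$taxonomyId)
  expect_identical(back$scientificName, db$scientificName)
  expect_identical(back$sequence, db$sequence)
  expect_true(562L %in% db$taxonomyId)
})

test_that("the mini CCD components are well-formed", {
  ccd <- makeMiniCcd()
  expect_true(all(c("ALA", "GLY", "LEU", "VAL", "CYS", "HOH", "NAG",
                    "MNL", "TPA") %in% names(ccd)))
  for (comp in ccd) expect_true(validObject(comp))
})

test_that("buildIdealChain realizes the requested torsions", {
  comps <- rep("ALA", 6)
  chain <- buildIdealChain(comps, phi = -57, psi = -47)
  expect_identical(nrow(chain), 6L * 5L)           # N CA C O CB
  dihedral <- getFromNamespace(".dihedral", "minidep")
  xyz <- function(i, nm) as.numeric(
    chain[chain$seqNum == i & chain$atomName == nm, c("x", "y", "z")])
  for (i in 2:5) {
    phi <- dihedral(xyz(i - 1, "C"), xyz(i, "N"), xyz(i, "CA"), xyz(i, "C"))
    psi <- dihedral(xyz(i, "N"), xyz(i, "CA"), xyz(i, "C"), xyz(i + 1, "N"))
    expect_equal(phi, -57, tolerance = 1e-6)
    expect_equal(psi, -47, tolerance = 1e-6)
  }
})
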