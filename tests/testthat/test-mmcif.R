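# mmCIF subset reader/writer and the deposition / CCD round trips.

test_that("mmCIF write/read round trip preserves a data block", {
  blk <- makeTable1Block()
  tmp <- tempfile(fileext = ".cif")
  on.exit(unlink(tmp))
  writeMmcif(blk, tmp)
  back <- readMmcif(tmp)
  expect_identical(sort(names(back@tables)), sort(names(blk@tables)))
  for (cat in names(blk@tables)) {
    a <- blk@tables[[cat]]; b <- back@tables[[cat]]
    expect_identical(sort(names(b)), sort(names(a)))
    for (col in names(a)) expect_identical(b[[col]], as.character(a[[col]]))
  }
})

test_that("values with spaces survive quoting", {
  blk <- makeTable1Block()
  src <- blk@tables$entity_src_gen
  expect_true(grepl(" ", src$pdbx_host_org_scientific_name[1]))
  txt <- writeMmcif(blk)
  back <- readMmcif(text = txt)
  expect_identical(back@tables$entity_src_gen$pdbx_host_org_scientific_name,
                   src$pdbx_host_org_scientific_name)
})

test_that("deposition write/read round trip preserves the model", {
  fx <- makeDeposition(character(0), seed = 3)
  dep <- fx$deposition
  tmp <- tempfile(fileext = ".cif")
  on.exit(unlink(tmp))
  writeDeposition(dep, tmp)
  back <- readDeposition(tmp)
  expect_identical(back@depId, dep@depId)
  expect_identical(back@sampleSequences, dep@sampleSequences)
  expect_identical(back@declarations, dep@declarations)
  expect_identical(nrow(back@atoms), nrow(dep@atoms))
  expect_identical(back@atoms$atomName, dep@atoms$atomName)
  expect_identical(back@atoms$compId, dep@atoms$compId)
  expect_identical(back@atoms$chain, dep@atoms$chain)
  expect_identical(back@atoms$seqNum, dep@atoms$seqNum)
  expect_equal(back@atoms$x, dep@atoms$x, tolerance = 1e-6)
  expect_equal(back@atoms$y, dep@atoms$y, tolerance = 1e-6)
  expect_equal(back@atoms$z, dep@atoms$z, tolerance = 1e-6)
})

test_that("CCD write/read round trip preserves every component", {
  ccd <- makeMiniCcd()
  tmp <- tempfile(fileext = ".cif")
  on.exit(unlink(tmp))
  writeCcd(ccd, tmp)
  back <- readCcd(tmp)
  expect_identical(sort(names(back)), sort(names(ccd)))
  for (id in names(ccd)) {
    a <- ccd[[id]]; b <- back[[id]]
    expect_identical(b@atoms$name, a@atoms$name)
    expect_identical(b@atoms$element, a@atoms$element)
    expect_identical(nrow(b@bonds), nrow(a@bonds))
    expect_identical(length(b@stereocenters), length(a@stereocenters))
    expect_equal(unname(b@idealXyz), unname(a@idealXyz), tolerance = 1e-5)
  }
})

test_that("fixture generation is deterministic per (plan, seed)", {
  # identical plan+seed => byte-identical serialization
  f1 <- makeDeposition(c("Atomic clashes"), seed = 5)
  f2 <- makeDeposition(c("Atomic clashes"), seed = 5)
  t1 <- tempfile(); t2 <- tempfile()
  on.exit(unlink(c(t1, t2)))
  writeDeposition(f1$deposition, t1)
  writeDeposition(f2$deposition, t2)
  expect_identical(readLines(t1), readLines(t2))
  expect_identical(f1$manifest, f2$manifest)
  # a different seed changes the sequence content
  f3 <- makeDeposition(c("Atomic clashes"), seed = 6)
  expect_false(identical(f1$deposition@sampleSequences,
                         f3$deposition@sampleSequences))
})
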