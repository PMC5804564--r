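# Sequence processor: coordinate-derived sequence, reference search,
# discrepancy annotation, chimera segmentation.

refdb2 <- makeRefDb(seed = 2)
base2 <- makeDeposition(character(0), seed = 2)

test_that("deriveCoordSequence reproduces the sample on the base fixture", {
  dep <- base2$deposition
  chainA <- dep@atoms[dep@atoms$chain == "A" &
                        !dep@atoms$compId %in% c("HOH", "MNL"), ,
                      drop = FALSE]
  res <- deriveCoordSequence(chainA, dep@sampleSequences[["A"]])
  expect_identical(res$coordSeq, dep@sampleSequences[["A"]])
  expect_identical(nrow(res$findings), 0L)
})

test_that("searchReferences ranks the true reference first", {
  dep <- base2$deposition
  hits <- searchReferences(dep@sampleSequences[["A"]], refdb2)
  expect_identical(hits$accession[1], "BASEP1")
  expect_equal(hits$score[1], 2 * nchar(dep@sampleSequences[["A"]]))
  if (nrow(hits) > 1) expect_true(all(diff(hits$score) <= 0))
})

test_that("reconcileSequences classifies declared and undeclared edits", {
  ref <- data.frame(accession = "REFX01", taxonomyId = 9606L,
                    scientificName = "Homo sapiens",
                    sequence = "ACDEFGHIKLMNPQRSTVWYACDEFGHIKL",
                    stringsAsFactors = FALSE)
  # identical sample: no annotations, no findings
  clean <- reconcileSequences(ref$sequence, ref = ref)
  expect_identical(nrow(clean$annotations), 0L)
  expect_identical(nrow(clean$findings), 0L)
  # one substitution, declared: a mutation annotation, no finding
  mutated <- sub("^ACDEF", "ACDEW", ref$sequence)
  dec <- reconcileSequences(mutated, ref = ref,
                            declarations = list(mutation = "F5W"))
  expect_identical(dec$annotations$class, "mutation")
  expect_equal(dec$annotations$start, 5)
  expect_identical(nrow(dec$findings), 0L)
  # the same substitution undeclared: a conflict needing correspondence
  undec <- reconcileSequences(mutated, ref = ref)
  expect_identical(undec$annotations$class, "conflict")
  expect_true(any(undec$findings$code == "correspondence_needed"))
  # an N-terminal hexahistidine span classifies as an expression tag
  tagged <- paste0("GSSHHHHHH", ref$sequence)
  tg <- reconcileSequences(tagged, ref = ref)
  expect_identical(tg$annotations$class, "expression tag")
  expect_equal(c(tg$annotations$start, tg$annotations$end), c(1, 9))
  # a terminal span without a tag motif is a cloning artifact
  art <- reconcileSequences(paste0(ref$sequence, "GPLGS"), ref = ref)
  expect_identical(art$annotations$class, "cloning artifact")
})

test_that("unmodeled coordinate gaps are annotated", {
  ref <- data.frame(accession = "REFX01", taxonomyId = 9606L,
                    scientificName = "Homo sapiens",
                    sequence = "ACDEFGHIKLMNPQRSTVWY",
                    stringsAsFactors = FALSE)
  res <- reconcileSequences(ref$sequence, coordSeq = "ACDEF---KLMNPQRSTVWY",
                            ref = ref)
  un <- res$annotations[res$annotations$class == "unmodeled", , drop = FALSE]
  expect_identical(nrow(un), 1L)
  expect_equal(c(un$start, un$end), c(6, 8))
})

test_that("the aligner matches the textbook oracle on random pairs", {
  ap <- getFromNamespace(".alignPair", "minidep")
  set.seed(101)
  for (k in 1:40) {
    p <- randomProtein(sample(1:50, 1))
    s <- randomProtein(sample(1:50, 1))
    for (ty in c("local", "overlap"))
      expect_equal(ap(p, s, type = ty)$score,
                   oracleAlignScore(p, s, type = ty),
                   info = sprintf("%s: %s vs %s", ty, p, s))
  }
})

test_that("segmentChimera recovers a planted swap and honors kappa = Inf", {
  cs <- makeChimeraCase(17)
  res <- segmentChimera(cs$sample, cs$refdb)
  expect_true(res$chimeric)
  expect_identical(res$segments$accession, c("HOSTAA", "DONORB", "HOSTAA"))
  expect_identical(res$segments$start[2], 80L)
  expect_identical(res$segments$end[2], 109L)
  # forbidding switches collapses to the best single-reference map
  res2 <- segmentChimera(cs$sample, cs$refdb, kappa = Inf)
  expect_false(res2$chimeric)
  expect_true(all(is.na(res2$segments$accession) |
                    res2$segments$accession == "HOSTAA"))
})

test_that("a sample with no reference support stays unassigned", {
  set.seed(7)
  cs <- makeChimeraCase(7)
  res <- segmentChimera(randomProtein(60), cs$refdb)
  expect_false(res$chimeric)
  expect_true(any(res$findings$code == "unassigned_segment"))
})
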