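# Structure annotator: symmetry, solvent repositioning, links, secondary
# structure, assemblies, renumbering, extended checks.

base4 <- makeDeposition(character(0), seed = 4)

test_that("cell orthogonalization and symmetry operators behave", {
  M <- cellOrthoMatrix(list(a = 40, b = 50, c = 60, alpha = 90, beta = 90,
                            gamma = 90))
  expect_equal(M, diag(c(40, 50, 60)), tolerance = 1e-9)
  expect_error(cellOrthoMatrix(list(a = -1, b = 50, c = 60, alpha = 90,
                                    beta = 90, gamma = 90)),
               class = "minidepArgumentError")
  expect_identical(length(spaceGroupOps("P 1")), 1L)
  expect_identical(length(spaceGroupOps("P 21")), 2L)
  expect_identical(length(spaceGroupOps("P 21 21 21")), 4L)
  expect_error(spaceGroupOps("F 9"), class = "minidepArgumentError")
  op <- parseSymop("-x,y+1/2,-z")
  expect_identical(renderSymop(op), "-x,y+1/2,-z")
  expect_equal(op$R, rbind(c(-1, 0, 0), c(0, 1, 0), c(0, 0, -1)))
  expect_equal(op$t, c(0, 0.5, 0))
})

test_that("a misplaced water is brought home to the identity image", {
  fx <- makeDeposition("misplaced_water", seed = 4)
  res <- repositionWaters(fx$deposition)
  expect_true(any(res$findings$code == "water_moved"))
  expect_identical(nrow(res$moved), 1L)
  expect_lt(res$moved$newDist, res$moved$oldDist)
  # repositioning is idempotent
  res2 <- repositionWaters(res$deposition)
  expect_identical(nrow(res2$findings), 0L)
})

test_that("repositioned waters sit at the brute-force image optimum", {
  # small module-level version of the acceptance property (5 seeded cases)
  dep <- base4$deposition
  cell <- list(a = 40, b = 50, c = 60, alpha = 90, beta = 90, gamma = 90)
  M <- cellOrthoMatrix(cell); Minv <- solve(M)
  ops <- spaceGroupOps("P 21")
  poly <- dep@atoms[!dep@atoms$compId %in% c("HOH", "MNL"), , drop = FALSE]
  polyXyz <- as.matrix(poly[, c("x", "y", "z")])
  set.seed(99)
  for (k in 1:5) {
    p <- c(runif(1, 0, 40), runif(1, 0, 50), runif(1, 0, 60))
    mod <- dep
    w <- mod@atoms$compId == "HOH" & mod@atoms$seqNum == 1L
    mod@atoms[w, c("x", "y", "z")] <- as.list(p)
    res <- repositionWaters(mod)
    newP <- as.numeric(res$deposition@atoms[w, c("x", "y", "z")])
    want <- oracleImageMin(p, polyXyz, M, Minv, ops)
    d <- sqrt(min(rowSums(sweep(polyXyz, 2, newP)^2)))
    expect_equal(d, want$d, tolerance = 1e-6)
  }
})

test_that("the base helix is assigned as one helix run", {
  dep <- base4$deposition
  chainA <- dep@atoms[dep@atoms$chain == "A" &
                        !dep@atoms$compId %in% c("HOH", "MNL"), ,
                      drop = FALSE]
  ss <- assignSecondaryStructure(chainA)
  states <- unname(ss$states)
  expect_identical(length(states), 30L)
  r <- rle(states)
  expect_identical(r$values, c("C", "H", "C"))
  expect_identical(r$lengths[2], 28L)
})

test_that("the clean base has no spurious covalent links", {
  expect_identical(nrow(generateLinks(base4$deposition)), 0L)
})

test_that("assembly expansion copies every chain under every operator", {
  dep <- base4$deposition
  one <- buildAssembly(dep)
  expect_identical(nrow(one$atoms), nrow(dep@atoms))
  expect_equal(one$atoms$x, dep@atoms$x)
  two <- buildAssembly(dep, ops = list(
    list(id = "1", R = diag(3), t = c(0, 0, 0)),
    list(id = "2", R = diag(3), t = c(0, 0, 20))))
  expect_identical(nrow(two$atoms), 2L * nrow(dep@atoms))
  expect_true(all(two$stoichiometry$copies == 2L))
  expect_error(buildAssembly(dep, ops = list(
    list(id = "1", R = matrix(2 * diag(3), 3), t = c(0, 0, 0)))),
    class = "minidepOperatorError")
})

test_that("hetero renumbering is deterministic and idempotent", {
  res <- renumberHeteros(base4$deposition)
  m <- res$map
  lig <- m[m$compId == "MNL", , drop = FALSE]
  expect_identical(lig$newChain, "A")
  expect_identical(lig$newSeqNum, 501L)
  wat <- m[m$compId == "HOH", , drop = FALSE]
  expect_identical(sort(wat$newSeqNum), 1001:1005)
  res2 <- renumberHeteros(res$deposition)
  expect_identical(res2$deposition@atoms, res$deposition@atoms)
})

test_that("extended checks catch planted coordinate defects", {
  ccd <- makeMiniCcd()
  expect_identical(nrow(extendedChecks(base4$deposition, ccd = ccd)), 0L)
  clash <- makeDeposition("Atomic clashes", seed = 4)
  expect_true(any(extendedChecks(clash$deposition, ccd = ccd)$code ==
                    "Atomic clashes"))
  zb <- makeDeposition("Zero B-factor", seed = 4)
  f <- extendedChecks(zb$deposition, ccd = ccd)
  expect_true(any(f$code == "Zero B-factor"))
  expect_identical(unique(f$severity[f$code == "Zero B-factor"]), "warning")
  tor <- makeDeposition("Unusual phi/psi torsion angles", seed = 4)
  expect_true(any(extendedChecks(tor$deposition, ccd = ccd)$code ==
                    "Unusual phi/psi torsion angles"))
})
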