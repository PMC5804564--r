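# Dictionary engine: schema parsing, range checks, block validation,
# key integrity.

schemaItem <- function(schema, name) {
  cat <- sub("\\..*$", "", name)
  items <- schema@categories[[cat]]@items
  items[[which(vapply(items, function(i) i@name, character(1)) == name)]]
}

test_that("the packaged schemas load with the expected shape", {
  core <- loadSchema(minidepSchemaFile("core"))
  dep <- loadSchema(minidepSchemaFile("deposition"))
  expect_true(all(c("entity", "entity_poly", "entity_src_gen", "atom_site",
                    "cell", "symmetry", "reflns") %in%
                    names(core@categories)))
  expect_true(all(names(core@categories) %in% names(dep@categories)))
  expect_true(all(c("exptl", "minidep_declaration") %in%
                    names(dep@categories)))
  rmerge <- schemaItem(core, "reflns.pdbx_Rmerge_I_obs")
  expect_identical(rmerge@typeCode, "float")
  expect_equal(rmerge@softRange, c(0.01, 0.2))
})

test_that("checkRange partitions the line into pass/soft/hard", {
  item <- schemaItem(loadSchema(minidepSchemaFile("core")),
                     "reflns.pdbx_Rmerge_I_obs")
  expect_null(checkRange(0.13, item))
  soft <- checkRange(0.7, item)
  expect_identical(soft$code, "soft_range")
  expect_identical(soft$severity, "warning")
  hard <- checkRange(1300, item)
  expect_identical(hard$code, "hard_range")
  expect_identical(hard$severity, "error")
  expect_identical(checkRange("not-a-number", item)$code, "type_violation")
  text <- schemaItem(loadSchema(minidepSchemaFile("core")),
                     "symmetry.space_group_name_H-M")
  expect_error(checkRange(1, text), class = "minidepTypeError")
})

test_that("deriveSoftLimits implements the three-sigma rule", {
  set.seed(11)
  for (k in 1:20) {
    x <- rnorm(sample(2:40, 1), mean = runif(1, -5, 5), sd = runif(1, .1, 3))
    expect_equal(deriveSoftLimits(x),
                 c(mean(x) - 3 * sd(x), mean(x) + 3 * sd(x)))
    expect_equal(deriveSoftLimits(x, k = 2),
                 c(mean(x) - 2 * sd(x), mean(x) + 2 * sd(x)))
  }
  expect_error(deriveSoftLimits(0.5), class = "minidepInsufficientData")
  expect_error(deriveSoftLimits(c(1, NA)),
               class = "minidepInsufficientData")
})

test_that("validateBlock flags type, enum, mandatory and limit defects", {
  schema <- loadSchema(minidepSchemaFile("deposition"))
  clean <- makeTable1Block()
  expect_identical(nrow(validateBlock(clean, loadSchema(
    minidepSchemaFile("core")))), 0L)

  bad <- clean
  bad@tables$entity_src_gen$pdbx_host_org_ncbi_taxonomy_id <- "five62"
  f <- validateBlock(bad, schema)
  expect_true("type_violation" %in% f$code)

  bad2 <- clean
  bad2@tables$exptl <- data.frame(method = "GUESSWORK",
                                  stringsAsFactors = FALSE)
  f2 <- validateBlock(bad2, schema)
  expect_true("enum_violation" %in% f2$code)

  bad3 <- clean
  bad3@tables$cell <- data.frame(length_a = "40", length_b = "?",
                                 length_c = "60", angle_alpha = "90",
                                 angle_beta = "90", angle_gamma = "90",
                                 stringsAsFactors = FALSE)
  f3 <- validateBlock(bad3, schema)
  expect_true("missing_mandatory" %in% f3$code)

  bad4 <- clean
  bad4@tables$reflns <- data.frame(pdbx_Rmerge_I_obs = "0.7",
                                   stringsAsFactors = FALSE)
  f4 <- validateBlock(bad4, schema)
  expect_true("soft_range" %in% f4$code)
  expect_identical(f4$severity[f4$code == "soft_range"], "warning")
})

test_that("checkKeys enforces parent/child integrity and key uniqueness", {
  schema <- loadSchema(minidepSchemaFile("core"))
  clean <- makeTable1Block()
  expect_identical(nrow(checkKeys(clean, schema)), 0L)

  orphan <- clean
  orphan@tables$entity_poly$entity_id <- "99"
  f <- checkKeys(orphan, schema)
  expect_true(any(f$code == "key_integrity"))

  dup <- clean
  dup@tables$entity <- rbind(dup@tables$entity, dup@tables$entity)
  f2 <- checkKeys(dup, schema)
  expect_true(any(f2$code == "key_integrity"))
})

test_that("schema write/load round trip is faithful", {
  schema <- loadSchema(minidepSchemaFile("deposition"))
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  writeSchema(schema, tmp)
  back <- loadSchema(tmp)
  expect_identical(names(back@categories), names(schema@categories))
  for (cat in names(schema@categories)) {
    a <- schema@categories[[cat]]; b <- back@categories[[cat]]
    expect_identical(b@keyItems, a@keyItems)
    expect_identical(vapply(b@items, function(i) i@name, character(1)),
                     vapply(a@items, function(i) i@name, character(1)))
  }
  r1 <- schemaItem(schema, "reflns.pdbx_Rmerge_I_obs")
  r2 <- schemaItem(back, "reflns.pdbx_Rmerge_I_obs")
  expect_equal(r2@softRange, r1@softRange)
  expect_equal(r2@hardRange, r1@hardRange)
})
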