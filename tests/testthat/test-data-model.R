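test_that("variable specs enforce role/level invariants", {
  expect_error(variableSpec("x", "binary", levels = c("a", "b", "c")),
               "exactly 2 levels")
  expect_error(variableSpec("x", "ordinal", levels = "one"), "at least 2")
  expect_error(variableSpec("x", "nominal", levels = c("a", "a")), "unique")
  expect_error(variableSpec("x", "continuous", levels = c("a", "b")),
               "must not declare levels")
  expect_error(variableSpec("x", "flavor"), "role")
  sp <- variableSpec("color", "ordinal", levels = c("J", "I", "H"))
  expect_identical(nCategories(sp), 3L)
})

test_that("schemas require a categorical target distinct from the conditional", {
  vars <- list(variableSpec("a", "binary", levels = c("0", "1")),
               variableSpec("b", "continuous"))
  expect_error(datasetSchema(vars, target = "b"), "binary, ordinal or nominal")
  expect_error(datasetSchema(vars, target = "zzz"), "not a declared")
  expect_error(datasetSchema(vars, target = "a", conditional = "a"),
               "differ from target")
  expect_s4_class(datasetSchema(vars, target = "a", conditional = "b"),
                  "DatasetSchema")
})

test_that("reading maps labels to schema-ordered codes and flags sentinels", {
  fix <- writeMixedFixtureCSV()
  on.exit(unlink(fix$path))
  rm <- readResponseTable(fix$path, fix$schema)
  v <- responseValues(rm); obs <- observedMask(rm)
  # first declared level -> code 0, in schema order not data order
  expect_identical(unname(v[1, "color"]), 0L)
  expect_identical(unname(v[6, "color"]), 3L)
  # sentinel "-1" and empty string both unobserved
  expect_false(obs[3, "color"])
  expect_false(obs[5, "color"])
  expect_identical(sum(!obs[, "hibp"]), 2L)
  # continuous/outcome carried in caseData; ignore dropped
  expect_setequal(colnames(caseData(rm)), c("age", "outcome"))
  expect_equal(caseData(rm)$age[1], 61)
  expect_identical(nCases(rm), 10L)
})

test_that("unknown labels and missing columns raise named errors", {
  fix <- writeMixedFixtureCSV()
  on.exit(unlink(fix$path))
  badSchema <- datasetSchema(list(
    variableSpec("color", "ordinal", levels = c("J", "I")),
    variableSpec("hibp", "binary", levels = c("no", "yes"))),
    target = "hibp")
  expect_error(readResponseTable(fix$path, badSchema),
               "column 'color', row 4: label 'H'")
  noCol <- datasetSchema(list(
    variableSpec("absent", "binary", levels = c("0", "1"))),
    target = "absent")
  expect_error(readResponseTable(fix$path, noCol), "absent")
})

test_that("write/read round trip reproduces codes and mask exactly", {
  fix <- writeMixedFixtureCSV()
  on.exit(unlink(fix$path))
  rm <- readResponseTable(fix$path, fix$schema)
  out <- tempfile(fileext = ".csv")
  on.exit(unlink(out), add = TRUE)
  writeResponseTable(rm, out)
  rt <- readResponseTable(out, fix$schema)
  expect_identical(responseValues(rt), responseValues(rm))
  expect_identical(observedMask(rt), observedMask(rm))
  expect_equal(caseData(rt), caseData(rm))
})

test_that("an empty matrix round-trips as a header-only file", {
  specs <- list(variableSpec("a", "binary", levels = c("0", "1")))
  rm <- responseMatrix(matrix(integer(), 0, 1), itemSpecs = specs)
  out <- tempfile(fileext = ".csv")
  on.exit(unlink(out))
  writeResponseTable(rm, out)
  expect_length(readLines(out), 1L)
  rt <- readResponseTable(out, datasetSchema(specs, target = "a"))
  expect_identical(nCases(rt), 0L)
})

test_that("coding is a per-item bijection that decoding inverts", {
  specs <- list(variableSpec("c", "nominal", levels = c("x", "y", "z")))
  set.seed(5)
  codes <- matrix(sample(0:2, 40, replace = TRUE), 40, 1)
  rm <- responseMatrix(codes, itemSpecs = specs)
  out <- tempfile(fileext = ".csv")
  on.exit(unlink(out))
  writeResponseTable(rm, out)
  labels <- read.csv(out, colClasses = "character")$c
  expect_identical(labels, c("x", "y", "z")[codes[, 1] + 1L])
  rt <- readResponseTable(out, datasetSchema(specs, target = "c"))
  expect_identical(responseValues(rt), responseValues(rm))
})

test_that("validateResponses surfaces degraded items and cases", {
  specs <- list(
    variableSpec("five", "ordinal", levels = as.character(0:4)),
    variableSpec("con", "binary", levels = c("0", "1")))
  values <- cbind(c(0L, 1L, 2L, 3L, 0L, 1L), rep(1L, 6))
  observed <- matrix(TRUE, 6, 2)
  observed[6, ] <- FALSE
  rm <- responseMatrix(values, observed, specs)
  f <- validateResponses(rm)
  expect_setequal(f$type,
                  c("unobserved_category", "constant_item", "all_missing_case"))
  # the constant binary item necessarily also has an unobserved category
  expect_setequal(f$item[f$type == "unobserved_category"], c("five", "con"))
  expect_identical(f$case[f$type == "all_missing_case"], 6L)
  # clean matrix: no findings
  clean <- responseMatrix(cbind(c(0L, 1L), c(1L, 0L)),
                          itemSpecs = list(
                            variableSpec("a", "binary", levels = c("0", "1")),
                            variableSpec("b", "binary", levels = c("0", "1"))))
  expect_identical(nrow(validateResponses(clean)), 0L)
})

test_that("schema YAML serialization round-trips", {
  fix <- writeMixedFixtureCSV()
  on.exit(unlink(fix$path))
  p <- tempfile(fileext = ".yml")
  on.exit(unlink(p), add = TRUE)
  writeSchema(fix$schema, p)
  s2 <- readSchema(p)
  expect_identical(s2@target, fix$schema@target)
  expect_identical(s2@conditional, fix$schema@conditional)
  expect_identical(vapply(s2@variables, function(v) v@name, ""),
                   vapply(fix$schema@variables, function(v) v@name, ""))
  expect_identical(s2@variables[[1]]@levels, fix$schema@variables[[1]]@levels)
})
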