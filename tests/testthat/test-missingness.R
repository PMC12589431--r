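smallRM <- function(n = 100, seed = 1) {
  bank <- twoPLBankFixture(J = 4, seed = seed)
  simulateResponses(simulateTheta(n, seed = seed + 1), bank, seed = seed + 2)
}

test_that("MCAR amputation removes the exact count, reproducibly", {
  rm <- smallRM(100)
  res <- induceMCAR(rm, "u1", 0.05, seed = 9)
  expect_identical(length(maskedCases(res$mask)), 5L)
  expect_identical(sum(!observedMask(res$data)[, "u1"]), 5L)
  res2 <- induceMCAR(rm, "u1", 0.05, seed = 9)
  expect_identical(maskedCases(res2$mask), maskedCases(res$mask))
  res3 <- induceMCAR(rm, "u1", 0.05, seed = 10)
  expect_false(identical(maskedCases(res3$mask), maskedCases(res$mask)))
  expect_error(induceMCAR(rm, "u1", 1.5, seed = 1), "fraction")
  # other columns untouched; inverse of the mask restores the original
  expect_identical(observedMask(res$data)[, -1], observedMask(rm)[, -1])
  expect_identical(restoreMask(res$data, rm, res$mask), rm)
})

test_that("MCAR cell selection is uniform over cases", {
  rm <- smallRM(20)
  hits <- integer(20)
  for (s in 1:10000) {
    m <- maskedCases(induceMCAR(rm, "u1", 0.25, seed = s)$mask)
    hits[m] <- hits[m] + 1L
  }
  expect_true(all(abs(hits / 10000 - 0.25) < 0.015))
})

test_that("MAR amputation removes the target from the top of the sorted order", {
  df <- data.frame(cond = 1:10, tgt = 101:110)
  res <- induceMAR(df, "tgt", "cond", 0.3)
  expect_identical(maskedCases(res$mask), c(8L, 9L, 10L))  # cond 10, 9, 8
  expect_true(all(is.na(res$data$tgt[8:10])))
  expect_identical(res$data$tgt[1:7], 101:107)   # original order preserved
  asc <- induceMAR(df, "tgt", "cond", 0.3, direction = "ascending")
  expect_identical(maskedCases(asc$mask), c(1L, 2L, 3L))
  half <- induceMAR(df, "tgt", "cond", 0.5)
  expect_identical(length(maskedCases(half$mask)), 5L)
  expect_error(induceMAR(df, "tgt", "tgt", 0.3), "differ")
})

test_that("MAR tie handling is a stable sort on (value, original index)", {
  df <- data.frame(cond = c(2, 2, 2, 1, 1), tgt = 1:5)
  res <- induceMAR(df, "tgt", "cond", 0.4)   # 2 cases; ties at cond=2
  expect_identical(maskedCases(res$mask), c(1L, 2L))
  res2 <- induceMAR(df, "tgt", "cond", 0.4)
  expect_identical(maskedCases(res2$mask), maskedCases(res$mask))
})

test_that("MAR on a ResponseMatrix can condition on an item or a caseData column", {
  rm <- smallRM(50, seed = 7)
  byItem <- induceMAR(rm, "u1", "u2", 0.2)
  expect_identical(length(maskedCases(byItem$mask)), 10L)
  rm2 <- responseMatrix(responseValues(rm), observedMask(rm), itemSpecs(rm),
                        caseData = data.frame(age = seq_len(50)))
  byCD <- induceMAR(rm2, "u1", "age", 0.2)
  expect_identical(maskedCases(byCD$mask), 41:50)
})

test_that("complete data give the degenerate Little result", {
  Y <- mvnFixture(100, seed = 3)
  lt <- littleMCARTest(Y)
  expect_true(lt$degenerate)
  expect_identical(unname(lt$parameter), 0)
  expect_identical(lt$p.value, 1)
})

test_that("the EM grand means reduce to ML estimates on complete data", {
  Y <- mvnFixture(200, seed = 4)
  Ym <- Y; Ym[1, 1] <- NA   # two patterns so the test runs
  lt <- littleMCARTest(Ym)
  expect_false(lt$degenerate)
  expect_identical(lt$patterns, 2L)
  expect_gte(unname(lt$statistic), 0)
  # with a single near-empty pattern the EM mean tracks the column means
  expect_equal(unname(lt$em$mu), unname(colMeans(Ym, na.rm = TRUE)),
               tolerance = 0.02)
})

test_that("Little's statistic is invariant to row order and column scaling", {
  Y <- mvnFixture(300, seed = 5)
  amp <- induceMAR(Y, "v1", "v2", 0.3)$data
  s0 <- littleMCARTest(amp)$statistic
  set.seed(6)
  s1 <- littleMCARTest(amp[sample(nrow(amp)), ])$statistic
  expect_equal(unname(s1), unname(s0), tolerance = 1e-6)
  sc <- amp
  sc[, "v3"] <- 10 * sc[, "v3"] - 4    # affine rescale of one column
  s2 <- littleMCARTest(sc)$statistic
  expect_equal(unname(s2), unname(s0), tolerance = 1e-4)
})

test_that("Little's test separates MAR from MCAR on a correlated fixture", {
  Y <- mvnFixture(500, rho = 0.7, seed = 8)
  mar <- induceMAR(Y, "v1", "v2", 0.3)$data
  expect_lt(littleMCARTest(mar)$p.value, 1e-6)
  mcar <- induceMCAR(Y, "v1", 0.3, seed = 9)$data
  expect_gt(littleMCARTest(mcar)$p.value, 0.001)
})

test_that("categorical matrices are encoded with nominal level indicators", {
  bank <- itemBank(list(twoPLItem(1.5, 0, name = "b"),
                        grmItem(1.5, c(-1, 1), name = "o"),
                        nrmItem(c(0, 1, 2), c(0, 0, 0), name = "nom")))
  rm <- simulateResponses(simulateTheta(300, seed = 10), bank, seed = 11)
  amp <- induceMCAR(rm, "b", 0.2, seed = 12)$data
  lt <- littleMCARTest(amp)
  expect_s3_class(lt, "htest")
  enc <- irtImpute:::encodeForLittle(amp)
  expect_setequal(colnames(enc), c("b", "o", "nom.1", "nom.2"))
  expect_identical(sum(is.na(enc[, "b"])), 60L)
})
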