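test_that("quadrature grids are normalized, symmetric and centred", {
  q <- buildQuadrature(3, 1)
  expect_equal(quadNodes(q), c(-1, 0, 1))
  expect_equal(quadWeights(q), dnorm(c(-1, 0, 1)) / sum(dnorm(c(-1, 0, 1))))
  q41 <- buildQuadrature(41, 5)
  w <- quadWeights(q41)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(w, rev(w))                       # symmetry of the normal prior
  expect_lt(abs(sum(w * quadNodes(q41))), 1e-12)
  expect_error(buildQuadrature(2), ">= 3")
  expect_error(buildQuadrature(41, -1), "positive")
})

test_that("a case's likelihood is the product over its observed items", {
  q <- buildQuadrature(11, 4)
  items <- list(twoPLItem(1, 0, name = "a"), grmItem(1.5, c(-1, 1), name = "b"))
  # single observed binary item, value 1
  L1 <- caseLikelihoodAtNodes(c(1L, NA), items, q)
  expect_equal(L1, prob2PL(quadNodes(q), 1, 0))
  # two observed items: equals the item-wise product computed independently
  L2 <- caseLikelihoodAtNodes(c(1L, 2L), items, q)
  oracle <- vapply(quadNodes(q), function(t)
    oracleItemProb(items[[1]], t, 1) * oracleItemProb(items[[2]], t, 2),
    numeric(1))
  expect_equal(L2, oracle, tolerance = 1e-12)
  expect_error(caseLikelihoodAtNodes(c(NA, NA), items, q), "prior-only")
})

fitSmallFixture <- function() {
  bank <- twoPLBankFixture(J = 5, seed = 11)
  rm <- simulateResponses(simulateTheta(300, seed = 12), bank, seed = 13)
  res <- induceMCAR(rm, "u1", 0.2, seed = 14)
  list(rm = res$data, bank = bank)
}

test_that("the EM trace is monotone and the final loglik matches the oracle", {
  fx <- fitSmallFixture()
  fit <- fitIRT(fx$rm)
  expect_true(fit@converged)
  expect_true(all(diff(fit@trace) > -1e-8))
  oracle <- oracleMarginalLoglik(fx$rm, irtItems(fit),
                                 quadNodes(irtQuadrature(fit)),
                                 quadWeights(irtQuadrature(fit)))
  expect_equal(fit@loglik, oracle, tolerance = 1e-8)
})

test_that("fits are invariant to case order and to codes hidden by the mask", {
  fx <- fitSmallFixture()
  fit <- fitIRT(fx$rm)
  # permute cases
  set.seed(21)
  perm <- sample(nCases(fx$rm))
  rmp <- responseMatrix(responseValues(fx$rm)[perm, ],
                        observedMask(fx$rm)[perm, ], itemSpecs(fx$rm))
  fitp <- fitIRT(rmp)
  expect_equal(itemParameters(fitp)$value, itemParameters(fit)$value,
               tolerance = 1e-10)
  # overwrite codes under the mask with arbitrary values
  v2 <- responseValues(fx$rm)
  v2[!observedMask(fx$rm)] <- 1L
  rm2 <- responseMatrix(v2, observedMask(fx$rm), itemSpecs(fx$rm))
  fit2 <- fitIRT(rm2)
  expect_identical(itemParameters(fit2)$value, itemParameters(fit)$value)
})

test_that("mixed item families are fitted jointly in one analysis", {
  bank <- itemBank(list(twoPLItem(1.5, 0, name = "b1"),
                        twoPLItem(1.0, -0.7, name = "b2"),
                        grmItem(1.8, c(-1, 0, 1), name = "o1"),
                        grmItem(1.2, c(-0.5, 0.8), name = "o2"),
                        nrmItem(c(0, 1, 2), c(0, 0.3, -0.3), name = "c1")))
  rm <- simulateResponses(simulateTheta(600, seed = 31), bank, seed = 32)
  fit <- fitIRT(rm)
  expect_true(fit@converged)
  expect_identical(vapply(irtItems(fit), itemFamily, ""),
                   c("2PL", "2PL", "GRM", "GRM", "NRM"))
  # slopes all recovered with the generating (positive) orientation
  expect_gt(irtItems(fit)[[1]]@a, 0)
  expect_gt(irtItems(fit)[[3]]@a, 0)
  # fitted GRM thresholds remain ordered
  expect_false(is.unsorted(irtItems(fit)[[3]]@thresholds))
})

test_that("items with declared-but-unobserved categories are refused unless collapsed", {
  specs <- list(variableSpec("t", "ordinal", levels = as.character(0:4)),
                variableSpec("u", "binary", levels = c("0", "1")))
  set.seed(41)
  n <- 200
  values <- cbind(sample(0:3, n, TRUE), sample(0:1, n, TRUE))  # level 4 never seen
  rm <- responseMatrix(values, itemSpecs = specs)
  expect_error(fitIRT(rm), "unobserved categories: t")
  fit <- fitIRT(rm, irtControl(collapseRare = TRUE, tol = 1e-4))
  expect_identical(nCategories(irtItems(fit)[[1]]), 4L)
  expect_identical(fit@itemSpecs[[1]]@levels, as.character(0:3))
})

test_that("refining the quadrature barely moves the marginal loglik", {
  fx <- fitSmallFixture()
  fit41 <- fitIRT(fx$rm, irtControl(nNodes = 41))
  fit81 <- fitIRT(fx$rm, irtControl(nNodes = 81))
  expect_lt(abs(fit41@loglik - fit81@loglik) / abs(fit81@loglik), 0.001)
})

test_that("hitting the iteration cap warns and flags non-convergence", {
  fx <- fitSmallFixture()
  expect_warning(fit <- fitIRT(fx$rm, irtControl(maxIter = 2L)),
                 "did not converge")
  expect_false(fit@converged)
  expect_true(all(diff(fit@trace) > -1e-8))
})

test_that("positive-slope constraint keeps 2PL slopes positive", {
  bank <- twoPLBankFixture(J = 6, seed = 51)
  rm <- simulateResponses(simulateTheta(400, seed = 52), bank, seed = 53)
  fit <- fitIRT(rm, irtControl(positiveSlopes = TRUE, tol = 1e-4))
  expect_true(all(vapply(irtItems(fit), function(i) i@a, 0) > 0))
})

test_that("fitted models serialize to a structured text file and back", {
  fx <- fitSmallFixture()
  fit <- fitIRT(fx$rm, irtControl(tol = 1e-4))
  p <- tempfile(fileext = ".yml")
  on.exit(unlink(p))
  writeIRTFit(fit, p)
  fit2 <- readIRTFit(p)
  expect_equal(itemParameters(fit2)$value, itemParameters(fit)$value,
               tolerance = 1e-8)
  expect_equal(fit2@loglik, fit@loglik, tolerance = 1e-8)
  # restored model scores identically
  th1 <- eapTheta(fx$rm, fit)
  th2 <- eapTheta(fx$rm, fit2)
  expect_equal(th1$eap, th2$eap, tolerance = 1e-8)
})
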