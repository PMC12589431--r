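flatFit <- function(J = 4) {
  items <- lapply(seq_len(J), function(j) twoPLItem(0, 0, name = paste0("f", j)))
  specs <- lapply(seq_len(J), function(j)
    variableSpec(paste0("f", j), "binary", levels = c("0", "1")))
  new("IRTFit", items = items, itemSpecs = specs,
      quadrature = buildQuadrature(41, 5), loglik = 0, trace = numeric(),
      converged = TRUE, nIter = 0L, control = irtControl())
}

test_that("flat items leave the posterior at the prior", {
  fit <- flatFit()
  est <- eapTheta(c(1L, 0L, 1L, 1L), fit)
  expect_equal(est$eap, 0, tolerance = 1e-12)
  expect_equal(est$psd, 1, tolerance = 0.01)  # grid-truncated prior SD
  expect_identical(est$nObserved, 4L)
})

test_that("EAP increases strictly with the raw score of a common-slope bank", {
  items <- lapply(1:5, function(j) twoPLItem(1.2, (j - 3) / 2, name = paste0("u", j)))
  specs <- lapply(1:5, function(j)
    variableSpec(paste0("u", j), "binary", levels = c("0", "1")))
  fit <- new("IRTFit", items = items, itemSpecs = specs,
             quadrature = buildQuadrature(41, 5), loglik = 0,
             trace = numeric(), converged = TRUE, nIter = 0L,
             control = irtControl())
  patterns <- as.matrix(expand.grid(rep(list(0:1), 5)))
  eaps <- apply(patterns, 1, function(p) eapTheta(as.integer(p), fit)$eap)
  score <- rowSums(patterns)
  groupMeans <- tapply(eaps, score, mean)
  expect_true(all(diff(groupMeans) > 0))
  # every pattern with a higher raw score outranks the lower-score mean
  expect_true(all(tapply(eaps, score, min)[-1] >
                  tapply(eaps, score, max)[-6]))
})

test_that("default-grid EAP matches 10,001-point fine-grid integration", {
  bank <- twoPLBankFixture(J = 8, seed = 61)
  rm <- simulateResponses(simulateTheta(50, seed = 62), bank, seed = 63)
  fit <- fitIRT(rm, irtControl(tol = 1e-4))
  est <- eapTheta(rm, fit)
  for (i in c(1, 7, 23, 50)) {
    fine <- oracleEAP(responseValues(rm)[i, ], irtItems(fit))
    expect_equal(est$eap[i], fine, tolerance = 1e-3)
  }
})

test_that("the binary 50% rule and its tie convention are honoured", {
  expect_identical(imputeBinary(c(0.49, 0.51)), c(0L, 1L))
  expect_message(v <- imputeBinary(0.5), "tie")
  expect_identical(v, 1L)
  expect_message(v0 <- imputeBinary(0.5, tie = 0L), "tie")
  expect_identical(v0, 0L)
  expect_error(imputeBinary(1.2), "probabilities")
})

test_that("polytomous imputation takes the argmax, lowest index on ties", {
  expect_identical(imputePolytomous(c(0.1, 0.7, 0.2)), 1L)
  expect_warning(v <- imputePolytomous(rep(0.25, 4)), "tie")
  expect_identical(v, 0L)
  expect_identical(imputePolytomous(c(0, 0, 1)), 2L)
  expect_error(imputePolytomous(c(0.5, 0.2)), "summing to 1")
})

imputeFixture <- function(frac = 0.1, targetSlope = 1.8, n = 800,
                          seed = 71) {
  items <- c(list(grmItem(targetSlope, c(-1.2, -0.3, 0.6, 1.4), name = "tgt")),
             lapply(1:6, function(j)
               twoPLItem(1.5, (j - 3.5) / 2, name = paste0("s", j))))
  bank <- itemBank(items)
  truth <- simulateResponses(simulateTheta(n, seed = seed), bank,
                             seed = seed + 1)
  amp <- induceMCAR(truth, "tgt", frac, seed = seed + 2)
  list(truth = truth, amp = amp$data, mask = amp$mask)
}

test_that("imputation passes observed cells through and beats the modal baseline", {
  fx <- imputeFixture()
  fit <- fitIRT(fx$amp, irtControl(tol = 1e-5))
  rep <- imputeDataset(fx$amp, fit, "tgt")
  # report covers exactly the amputed cells
  expect_identical(rep@cases, maskedCases(fx$mask))
  expect_true(all(abs(rowSums(rep@probs) - 1) < 1e-12))
  f1 <- scoreImputation(rep, fx$truth, "tgt")$aggregate
  base <- scoreImputation(modalBaseline(fx$amp, "tgt"), fx$truth, "tgt")$aggregate
  expect_gt(f1, base)
  # applying the report completes the matrix
  done <- applyImputation(fx$amp, rep)
  expect_true(all(observedMask(done)[, "tgt"]))
  untouched <- observedMask(fx$amp)[, "tgt"]
  expect_identical(responseValues(done)[untouched, "tgt"],
                   responseValues(fx$amp)[untouched, "tgt"])
})

test_that("a case with no observed items is imputed from the prior and flagged", {
  fx <- imputeFixture()
  obs <- observedMask(fx$amp)
  blank <- maskedCases(fx$mask)[1]
  obs[blank, ] <- FALSE
  rm <- responseMatrix(responseValues(fx$amp), obs, itemSpecs(fx$amp))
  fit <- fitIRT(rm, irtControl(tol = 1e-4))
  rep <- imputeDataset(rm, fit, "tgt")
  i <- match(blank, rep@cases)
  expect_true(rep@priorOnly[i])
  expect_equal(rep@theta$eap[i], 0, tolerance = 1e-10)
})

test_that("imputations are blind to the outcome column", {
  fx <- imputeFixture()
  cd <- data.frame(outcome = rnorm(nCases(fx$amp)))
  rm1 <- responseMatrix(responseValues(fx$amp), observedMask(fx$amp),
                        itemSpecs(fx$amp), caseData = cd)
  cd2 <- data.frame(outcome = sample(cd$outcome))
  rm2 <- responseMatrix(responseValues(fx$amp), observedMask(fx$amp),
                        itemSpecs(fx$amp), caseData = cd2)
  fit <- fitIRT(rm1, irtControl(tol = 1e-5))
  rep1 <- imputeDataset(rm1, fit, "tgt")
  rep2 <- imputeDataset(rm2, fit, "tgt")
  expect_identical(rep1@values, rep2@values)
  expect_identical(rep1@probs, rep2@probs)
  # determinism: repeating the whole scoring gives bitwise-equal output
  rep3 <- imputeDataset(rm1, fit, "tgt")
  expect_identical(rep1@values, rep3@values)
})

test_that("posterior-marginal probabilities remain a valid alternative", {
  fx <- imputeFixture()
  fit <- fitIRT(fx$amp, irtControl(tol = 1e-5))
  repP <- imputeDataset(fx$amp, fit, "tgt", method = "posterior")
  expect_true(all(abs(rowSums(repP@probs) - 1) < 1e-12))
  repD <- imputeDataset(fx$amp, fit, "tgt")
  # plug-in and posterior probabilities agree closely for informative cases
  expect_lt(max(abs(repP@probs - repD@probs)), 0.25)
})

test_that("imputation accuracy degrades as the target's slope shrinks", {
  # balanced binary target (b = 0): the marginal split stays 50/50 at any
  # slope, so accuracy differences reflect information content alone
  acc <- vapply(c(2.0, 1.0, 0.25), function(a) {
    items <- c(list(twoPLItem(a, 0, name = "tgt")),
               lapply(1:6, function(j)
                 twoPLItem(1.5, (j - 3.5) / 2, name = paste0("s", j))))
    truth <- simulateResponses(simulateTheta(1500, seed = 81),
                               itemBank(items), seed = 82)
    amp <- induceMCAR(truth, "tgt", 0.3, seed = 83)$data
    fit <- fitIRT(amp, irtControl(tol = 1e-5))
    rep <- imputeDataset(amp, fit, "tgt")
    j <- match("tgt", itemNames(truth))
    mean(rep@values == responseValues(truth)[rep@cases, j])
  }, numeric(1))
  expect_true(all(diff(acc) <= 0))
})
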