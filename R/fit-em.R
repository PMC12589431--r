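#' @include quadrature.R
NULL

#' Fit settings for marginal maximum likelihood
#'
#' @param nNodes Number of quadrature nodes (default 41).
#' @param bound Half-width of the quadrature grid (default 5).
#' @param tol EM stopping rule: absolute change in the marginal
#'   log-likelihood (default 1e-6).
#' @param maxIter Maximum EM iterations (default 500).
#' @param positiveSlopes If `TRUE`, constrain 2PL slopes to be positive
#'   (log-parameterized).  GRM slopes are always positive -- a negative
#'   common slope with ordered thresholds would produce negative category
#'   probabilities; reversing the category order is the equivalent model.
#'   NRM category slopes are unconstrained (the first is fixed at 0).
#' @param collapseRare If `TRUE`, declared categories that never occur
#'   among observed cells are collapsed out of the affected item before
#'   estimation (codes remapped, levels dropped); if `FALSE` (default)
#'   such items are refused with an error, surfacing the problem.
#' @param mMaxit Iteration cap of the per-item M-step optimizer.
#' @return A named list of settings for [fitIRT()].
#' @export
irtControl <- function(nNodes = 41L, bound = 5, tol = 1e-6, maxIter = 500L,
                       positiveSlopes = FALSE, collapseRare = FALSE,
                       mMaxit = 100L) {
  list(nNodes = as.integer(nNodes), bound = bound, tol = tol,
       maxIter = as.integer(maxIter), positiveSlopes = positiveSlopes,
       collapseRare = collapseRare, mMaxit = as.integer(mMaxit))
}

#' Likelihood of one response pattern at the quadrature nodes
#'
#' The conditional likelihood `L(theta_q)` of a single case: the product
#' over its observed items of the probability of the observed category.
#' Unobserved items contribute a factor of 1 (likelihood restriction to
#' observed cells), which is how missing responses are handled throughout.
#'
#' @param responses Integer vector of category codes (`0..K_i-1`), `NA`
#'   marking unobserved cells; one entry per item.
#' @param items List of item objects aligned with `responses`.
#' @param quad A [Quadrature-class].
#' @return Numeric vector of likelihood values, one per node.
#' @export
caseLikelihoodAtNodes <- function(responses, items, quad) {
  stopIfNot(length(responses) == length(items),
            "one response per item required")
  obs <- which(!is.na(responses))
  stopIfNot(length(obs) > 0L,
            "all responses unobserved: route this case to prior-only scoring")
  L <- rep(1, length(quad@nodes))
  for (j in obs) {
    P <- categoryProbs(items[[j]], quad@nodes)
    L <- L * P[, responses[j] + 1L]
  }
  L
}

# n x Q likelihood matrix over all cases (rows with no observations give 1).
likelihoodMatrix <- function(values, observed, items, nodes) {
  n <- nrow(values)
  L <- matrix(1, n, length(nodes))
  for (j in seq_along(items)) {
    idx <- which(observed[, j])
    if (!length(idx)) next
    P <- categoryProbs(items[[j]], nodes)          # Q x K
    L[idx, ] <- L[idx, ] * t(P)[values[idx, j] + 1L, , drop = FALSE]
  }
  L
}

## ---- per-family parameter transforms for the M-step -----------------------

packItem <- function(item, positiveSlopes) {
  if (is(item, "TwoPLItem")) {
    if (positiveSlopes) c(log(max(item@a, 1e-6)), item@b) else c(item@a, item@b)
  } else if (is(item, "GRMItem")) {
    th <- item@thresholds
    gaps <- diff(th)
    c(log(max(item@a, 1e-6)), th[1L],
      if (length(gaps)) log(pmax(gaps, 1e-4)))
  } else {
    c(item@slopes[-1L], item@intercepts[-1L])
  }
}

unpackItem <- function(par, item, positiveSlopes) {
  if (is(item, "TwoPLItem")) {
    a <- if (positiveSlopes) exp(par[1L]) else par[1L]
    twoPLItem(a, par[2L], name = item@name)
  } else if (is(item, "GRMItem")) {
    K1 <- length(item@thresholds)
    th <- par[2L]
    if (K1 > 1L) th <- th[1L] + c(0, cumsum(exp(par[3:(K1 + 1L)])))
    grmItem(exp(par[1L]), th, name = item@name)
  } else {
    K <- length(item@slopes)
    nrmItem(c(0, par[seq_len(K - 1L)]), c(0, par[K:(2L * (K - 1L))]),
            name = item@name)
  }
}

# Expected complete-data negative log-likelihood of one item given the
# E-step's expected category counts r (Q x K) at the quadrature nodes.
mStepObjective <- function(par, item, r, nodes, positiveSlopes) {
  it <- tryCatch(unpackItem(par, item, positiveSlopes), error = function(e) NULL)
  if (is.null(it)) return(1e300)
  P <- categoryProbs(it, nodes)
  v <- -sum(r * log(pmax(P, 1e-300)))
  if (!is.finite(v)) 1e300 else v
}

## ---- initialization -------------------------------------------------------

initItem <- function(spec, codes, n) {
  K <- length(spec@levels)
  tab <- tabulate(codes + 1L, nbins = K)
  p <- clampProp(tab / sum(tab), sum(tab))
  if (spec@role == "binary") {
    twoPLItem(1, -stats::qlogis(p[2L]), name = spec@name)
  } else if (spec@role == "ordinal") {
    pAbove <- clampProp(rev(cumsum(rev(p)))[-1L], sum(tab))   # P(U >= k), k=1..K-1
    th <- -stats::qlogis(pAbove)
    for (k in seq_along(th)[-1L])
      th[k] <- max(th[k], th[k - 1L] + 1e-3)
    grmItem(1, th, name = spec@name)
  } else {
    # small spread of starting slopes: an all-zero start is a stationary
    # point of the EM map for all-nominal banks (posterior = prior makes
    # the slope gradient vanish by quadrature symmetry)
    nrmItem(0.25 * (seq_len(K) - 1L), c(0, log(p[-1L] / p[1L])),
            name = spec@name)
  }
}

collapseUnobserved <- function(values, observed, specs) {
  for (j in seq_along(specs)) {
    sp <- specs[[j]]
    v <- values[observed[, j], j]
    seen <- sort(unique(v))
    if (length(seen) == length(sp@levels)) next
    remap <- match(values[, j], seen) - 1L
    values[, j] <- remap
    specs[[j]] <- variableSpec(sp@name, sp@role, levels = sp@levels[seen + 1L],
                               missingSentinel = sp@missingSentinel)
  }
  list(values = values, specs = specs)
}

#' Fit item parameters by marginal maximum likelihood
#'
#' Bock-Aitkin EM over a fixed quadrature grid with a standard-normal
#' latent-trait prior.  The E-step computes every case's posterior over
#' the nodes (prior weight times the case's conditional likelihood,
#' normalized) and accumulates expected per-node category counts for each
#' item; the M-step re-maximizes each item's expected complete-data
#' log-likelihood by quasi-Newton optimization (GRM threshold order is
#' maintained by optimizing log threshold gaps; the NRM first-category
#' constraint is held fixed).  Missing responses contribute nothing to the
#' likelihood.  Mixed item families are fitted jointly in one analysis.
#'
#' @param x A validated [ResponseMatrix-class]; every item needs at least
#'   two observed categories (see `collapseRare` in [irtControl()]).
#' @param control Settings from [irtControl()].
#' @return An [IRTFit-class] with a non-decreasing log-likelihood trace.
#'   Non-convergence within `maxIter` returns the model with
#'   `converged = FALSE` and a warning.
#' @examples
#' bank <- itemBank(list(twoPLItem(1.5, 0, name = "u1"),
#'                       twoPLItem(1.0, -0.5, name = "u2"),
#'                       twoPLItem(2.0, 0.5, name = "u3")))
#' rm <- simulateResponses(simulateTheta(300, seed = 7), bank, seed = 8)
#' fit <- fitIRT(rm, irtControl(tol = 1e-4))
#' fit
#' @export
fitIRT <- function(x, control = irtControl()) {
  stopIfNot(is(x, "ResponseMatrix"), "'x' must be a ResponseMatrix")
  values <- x@values; observed <- x@observed; specs <- x@itemSpecs
  values[!observed] <- NA_integer_

  nObsCat <- vapply(seq_along(specs), function(j)
    length(unique(values[observed[, j], j])), integer(1L))
  stopIfNot(all(nObsCat >= 2L),
            "item(s) with fewer than 2 observed categories: %s",
            paste(specNames(specs)[nObsCat < 2L], collapse = ", "))
  unobserved <- vapply(seq_along(specs), function(j)
    nObsCat[j] < length(specs[[j]]@levels), logical(1L))
  if (any(unobserved)) {
    if (!control$collapseRare)
      stop(sprintf(paste("item(s) with declared but unobserved categories: %s;",
                         "collapse them explicitly or set collapseRare = TRUE"),
                   paste(specNames(specs)[unobserved], collapse = ", ")),
           call. = FALSE)
    cl <- collapseUnobserved(values, observed, specs)
    values <- cl$values; specs <- cl$specs
  }

  quad <- buildQuadrature(control$nNodes, control$bound)
  nodes <- quad@nodes; w <- quad@weights
  n <- nrow(values); Q <- length(nodes)

  items <- lapply(seq_along(specs), function(j)
    initItem(specs[[j]], values[observed[, j], j], n))
  obsIdx <- lapply(seq_along(specs), function(j) which(observed[, j]))

  trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  nIter <- 0L

  for (it in 0:control$maxIter) {
    L <- likelihoodMatrix(values, observed, items, nodes)
    Li <- drop(L %*% w)
    if (any(!is.finite(Li)) || any(Li <= 0)) {
      culprit <- diagnoseZeroLikelihood(values, observed, items, nodes)
      stop(sprintf("non-finite marginal likelihood%s",
                   if (nzchar(culprit)) paste0(" (item '", culprit, "')") else ""),
           call. = FALSE)
    }
    ll <- sum(log(Li))
    trace <- c(trace, ll)
    if (it > 0L && abs(ll - prev) < control$tol) { converged <- TRUE; break }
    if (it == control$maxIter) break
    prev <- ll
    nIter <- it + 1L

    post <- L * rep(w, each = n)
    post <- post / Li

    for (j in seq_along(items)) {
      idx <- obsIdx[[j]]
      K <- nCategories(items[[j]])
      r <- matrix(0, Q, K)
      vj <- values[idx, j]
      for (k in seq_len(K))
        r[, k] <- .colSums(post[idx[vj == k - 1L], , drop = FALSE],
                           sum(vj == k - 1L), Q)
      par0 <- packItem(items[[j]], control$positiveSlopes)
      f0 <- mStepObjective(par0, items[[j]], r, nodes, control$positiveSlopes)
      opt <- tryCatch(
        stats::optim(par0, mStepObjective, item = items[[j]], r = r,
                     nodes = nodes, positiveSlopes = control$positiveSlopes,
                     method = "BFGS", control = list(maxit = control$mMaxit)),
        error = function(e) NULL)
      if (!is.null(opt) && is.finite(opt$value) && opt$value <= f0)
        items[[j]] <- unpackItem(opt$par, items[[j]], control$positiveSlopes)
    }
  }

  if (!converged)
    warning(sprintf("EM did not converge in %d iterations (last change %.3g)",
                    control$maxIter, abs(trace[length(trace)] - prev)),
            call. = FALSE)
  new("IRTFit", items = items, itemSpecs = specs, quadrature = quad,
      loglik = trace[length(trace)], trace = trace, converged = converged,
      nIter = nIter, control = control)
}

# Best-effort identification of an item driving a zero likelihood.
diagnoseZeroLikelihood <- function(values, observed, items, nodes) {
  for (j in seq_along(items)) {
    P <- categoryProbs(items[[j]], nodes)
    codes <- unique(values[observed[, j], j])
    if (any(!is.finite(P)) ||
        any(vapply(codes, function(k) all(P[, k + 1L] <= 0), logical(1L))))
      return(items[[j]]@name)
  }
  ""
}

#' @describeIn fitIRT Fitted item objects.
#' @param fit An [IRTFit-class].
#' @export
irtItems <- function(fit) fit@items

#' @describeIn fitIRT Quadrature grid of the fit.
#' @export
irtQuadrature <- function(fit) fit@quadrature

#' Tidy table of fitted item parameters
#'
#' @param fit An [IRTFit-class].
#' @return A data frame with one row per item parameter: columns `item`,
#'   `family`, `parameter`, `value`.
#' @export
itemParameters <- function(fit) {
  rows <- lapply(fit@items, function(it) {
    if (is(it, "TwoPLItem"))
      data.frame(item = it@name, family = "2PL",
                 parameter = c("a", "b"), value = c(it@a, it@b))
    else if (is(it, "GRMItem"))
      data.frame(item = it@name, family = "GRM",
                 parameter = c("a", paste0("b", seq_along(it@thresholds))),
                 value = c(it@a, it@thresholds))
    else
      data.frame(item = it@name, family = "NRM",
                 parameter = c(paste0("a", seq_along(it@slopes)),
                               paste0("c", seq_along(it@intercepts))),
                 value = c(it@slopes, it@intercepts))
  })
  do.call(rbind, rows)
}

#' @export
setMethod("show", "IRTFit", function(object) {
  fams <- table(vapply(object@items, itemFamily, character(1L)))
  cat(sprintf("IRTFit: %d items (%s); logLik %.4f; %d EM iterations%s\n",
              length(object@items),
              paste(sprintf("%d %s", fams, names(fams)), collapse = ", "),
              object@loglik, object@nIter,
              if (object@converged) "" else " [NOT converged]"))
})

#' @importFrom stats logLik
#' @export
logLik.IRTFit <- function(object, ...) {
  val <- object@loglik
  attr(val, "df") <- sum(vapply(object@items, function(it)
    length(packItem(it, FALSE)), integer(1L)))
  class(val) <- "logLik"
  val
}

#' Serialize a fitted model to a structured text file
#'
#' Writes the fitted items (as an item-bank YAML section), quadrature
#' settings and convergence information; [readIRTFit()] restores an
#' [IRTFit-class] usable for scoring and imputation (the EM trace is
#' preserved).
#'
#' @param fit An [IRTFit-class].
#' @param path Output file path.
#' @return `path` invisibly; `readIRTFit` returns the restored fit.
#' @export
writeIRTFit <- function(fit, path) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  writeItemBank(new("ItemBank", items = fit@items, specs = fit@itemSpecs), tmp)
  bank <- yaml::read_yaml(tmp)
  cfg <- list(items = bank$items,
              quadrature = list(nNodes = length(fit@quadrature@nodes),
                                bound = max(fit@quadrature@nodes)),
              loglik = fit@loglik, trace = as.list(fit@trace),
              converged = fit@converged, nIter = fit@nIter)
  yaml::write_yaml(cfg, path, precision = 12L)
  invisible(path)
}

#' @rdname writeIRTFit
#' @export
readIRTFit <- function(path) {
  cfg <- yaml::read_yaml(path)
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  yaml::write_yaml(list(items = cfg$items), tmp, precision = 12L)
  bank <- readItemBank(tmp)
  new("IRTFit", items = bank@items, itemSpecs = bank@specs,
      quadrature = buildQuadrature(cfg$quadrature$nNodes, cfg$quadrature$bound),
      loglik = cfg$loglik, trace = unlist(cfg$trace),
      converged = cfg$converged, nIter = as.integer(cfg$nIter),
      control = list())
}
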