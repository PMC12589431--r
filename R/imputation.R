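#' @include scoring.R
NULL

#' Impute a binary cell from its model-implied probability
#'
#' The 50% rule for binary items: probability of category 1 below 0.5
#' imputes 0, above 0.5 imputes 1.  An exact tie at 0.5 imputes the value
#' of `tie` (default 1) and is logged with a message.
#'
#' @param p1 Probability of category 1, in `[0, 1]` (vectorized).
#' @param tie Code returned at an exact 0.5 tie (0 or 1; default 1).
#' @return Integer code(s) 0 or 1.
#' @examples
#' imputeBinary(c(0.49, 0.51))  # 0, 1
#' @export
imputeBinary <- function(p1, tie = 1L) {
  stopIfNot(all(is.finite(p1)) && all(p1 >= 0) && all(p1 <= 1),
            "'p1' must be probabilities in [0, 1]")
  stopIfNot(tie %in% c(0L, 1L), "'tie' must be 0 or 1")
  out <- ifelse(p1 < 0.5, 0L, 1L)
  atTie <- p1 == 0.5
  if (any(atTie)) {
    out[atTie] <- as.integer(tie)
    message(sprintf("%d exact 0.5 tie(s) imputed as %d", sum(atTie), tie))
  }
  as.integer(out)
}

#' Impute a polytomous cell from its category probability vector
#'
#' The highest-probability category is assigned.  Ties resolve to the
#' lowest category index, with a warning.
#'
#' @param probs Numeric probability vector summing to 1 (within 1e-6).
#' @return Integer category code (0-based).
#' @examples
#' imputePolytomous(c(0.1, 0.7, 0.2))  # 1
#' @export
imputePolytomous <- function(probs) {
  stopIfNot(all(is.finite(probs)) && all(probs >= 0) &&
              abs(sum(probs) - 1) < 1e-6,
            "'probs' must be a probability vector summing to 1")
  top <- which(probs == max(probs))
  if (length(top) > 1L)
    warning(sprintf("probability tie among categories %s; lowest assigned",
                    paste(top - 1L, collapse = ", ")), call. = FALSE)
  as.integer(top[1L] - 1L)
}

#' Impute the missing cells of a target item
#'
#' For every case whose target cell is unobserved, the case's latent trait
#' is scored by EAP from its *other* observed items (the missing target
#' contributes nothing to the likelihood), the target item's category
#' probabilities are evaluated at that score under the fitted family, and
#' the binary 50% rule or polytomous argmax rule assigns the imputed code.
#' Observed target cells pass through untouched; outcome and continuous
#' `caseData` columns are never consulted, so the imputations cannot leak
#' the outcome.
#'
#' Cases with no observed items at all are scored at the prior mean and
#' flagged in the report's `priorOnly` slot.
#'
#' @param x The [ResponseMatrix-class] the model was fitted to (same item
#'   layout).
#' @param fit A fitted [IRTFit-class].
#' @param target Name of the target item.
#' @param tie Binary tie rule passed to [imputeBinary()].
#' @param method `"plugin"` (default) evaluates category probabilities at
#'   the EAP point estimate; `"posterior"` integrates them over the full
#'   theta posterior instead.
#' @return An [ImputationReport-class]; use [applyImputation()] to obtain
#'   the completed matrix.
#' @export
imputeDataset <- function(x, fit, target, tie = 1L,
                          method = c("plugin", "posterior")) {
  method <- match.arg(method)
  stopIfNot(is(x, "ResponseMatrix"), "'x' must be a ResponseMatrix")
  stopIfNot(is(fit, "IRTFit"), "'fit' must be an IRTFit")
  j <- match(target, specNames(fit@itemSpecs))
  stopIfNot(!is.na(j), "target '%s' is not among the fitted items", target)
  stopIfNot(nItems(x) == length(fit@items),
            "matrix and fit disagree on the number of items")

  cases <- which(!x@observed[, j])
  K <- nCategories(fit@items[[j]])
  spec <- fit@itemSpecs[[j]]
  if (!length(cases)) {
    return(new("ImputationReport", target = target, cases = integer(),
               values = integer(), probs = matrix(numeric(), 0L, K),
               theta = data.frame(eap = numeric(), psd = numeric(),
                                  nObserved = numeric()),
               priorOnly = logical()))
  }
  sub <- x@values[cases, , drop = FALSE]
  subObs <- x@observed[cases, , drop = FALSE]
  sub[!subObs] <- NA_integer_
  post <- posteriorMatrix(sub, subObs, fit@items, fit@quadrature)
  theta <- eapFromPosterior(post, fit@quadrature@nodes, rowSums(subObs))
  probs <- if (method == "plugin")
    categoryProbs(fit@items[[j]], theta$eap)
  else
    post %*% categoryProbs(fit@items[[j]], fit@quadrature@nodes)
  values <- if (spec@role == "binary") imputeBinary(probs[, 2L], tie = tie)
            else vapply(seq_len(nrow(probs)),
                        function(i) imputePolytomous(probs[i, ]), integer(1L))
  new("ImputationReport", target = target, cases = as.integer(cases),
      values = values, probs = probs, theta = theta,
      priorOnly = theta$nObserved == 0)
}

#' @describeIn imputeDataset Imputed codes, named by case index.
#' @param report An [ImputationReport-class].
#' @export
imputedValues <- function(report) {
  stats::setNames(report@values, report@cases)
}

#' @describeIn imputeDataset Per-cell probability report as a data frame
#'   (one row per imputed cell: case, EAP score, category probabilities,
#'   imputed code).
#' @export
imputationProbs <- function(report) {
  df <- data.frame(case = report@cases, eap = report@theta$eap,
                   psd = report@theta$psd, imputed = report@values,
                   priorOnly = report@priorOnly)
  probs <- as.data.frame(report@probs)
  colnames(probs) <- paste0("p", seq_len(ncol(probs)) - 1L)
  cbind(df, probs)
}

#' Fill imputed values back into a response matrix
#'
#' @param x The amputed [ResponseMatrix-class].
#' @param report An [ImputationReport-class] from [imputeDataset()].
#' @return A completed [ResponseMatrix-class]: the target's previously
#'   missing cells carry the imputed codes and are marked observed.
#' @export
applyImputation <- function(x, report) {
  j <- itemIndex(x, report@target)
  values <- x@values; observed <- x@observed
  values[report@cases, j] <- report@values
  observed[report@cases, j] <- TRUE
  responseMatrix(values, observed, x@itemSpecs, x@caseData)
}

setMethod("show", "ImputationReport", function(object) {
  cat(sprintf("ImputationReport: %d cell(s) of '%s' imputed%s\n",
              length(object@cases), object@target,
              if (any(object@priorOnly))
                sprintf(" (%d from the prior alone)", sum(object@priorOnly))
              else ""))
  if (length(object@cases))
    print(utils::head(imputationProbs(object), 5L))
})
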