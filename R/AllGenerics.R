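#' @include AllGenerics.R
NULL

#' Category response probabilities of an item
#'
#' Evaluates the item response function of a fitted or hand-specified item at
#' one or more latent-trait values, returning the probability of every
#' response category.
#'
#' @param item An item object: [TwoPLItem-class], [GRMItem-class] or
#'   [NRMItem-class].
#' @param theta Numeric vector of latent-trait values.
#' @return A numeric matrix with `length(theta)` rows and one column per
#'   category; every row sums to 1.
#' @seealso [prob2PL()], [grmCategoryProbs()], [nrmCategoryProbs()]
#' @export
setGeneric("categoryProbs", function(item, theta) standardGeneric("categoryProbs"))

#' Number of response categories of an item or variable
#'
#' @param x An item object or [VariableSpec-class].
#' @return Integer count of categories.
#' @export
setGeneric("nCategories", function(x) standardGeneric("nCategories"))

#' Model family label of an item
#'
#' @param x An item object.
#' @return `"2PL"`, `"GRM"` or `"NRM"`.
#' @export
setGeneric("itemFamily", function(x) standardGeneric("itemFamily"))

#' @rdname ResponseMatrix-class
#' @export
setGeneric("responseValues", function(x) standardGeneric("responseValues"))

#' @rdname ResponseMatrix-class
#' @export
setGeneric("observedMask", function(x) standardGeneric("observedMask"))

#' @rdname ResponseMatrix-class
#' @export
setGeneric("itemSpecs", function(x) standardGeneric("itemSpecs"))

#' @rdname ResponseMatrix-class
#' @export
setGeneric("caseData", function(x) standardGeneric("caseData"))

#' @rdname ResponseMatrix-class
#' @export
setGeneric("itemNames", function(x) standardGeneric("itemNames"))

#' @rdname ResponseMatrix-class
#' @export
setGeneric("nCases", function(x) standardGeneric("nCases"))

#' @rdname ResponseMatrix-class
#' @export
setGeneric("nItems", function(x) standardGeneric("nItems"))

#' Expected a posteriori latent-trait scores
#'
#' Computes each case's posterior mean and posterior standard deviation of
#' the latent trait given its observed responses, integrating over the
#' model's quadrature grid with the standard-normal prior.  Cases with no
#' observed (informative) responses receive the prior mean and SD.
#'
#' @param object A [ResponseMatrix-class], or a single integer response
#'   vector coded `0..K-1` with `NA` marking unobserved cells.
#' @param fit A fitted [IRTFit-class] model.
#' @return A data frame with columns `eap`, `psd`, `nObserved`, one row per
#'   case.
#' @export
setGeneric("eapTheta", function(object, fit) standardGeneric("eapTheta"))

#' Induce missing-completely-at-random missingness in one column
#'
#' Removes a fixed fraction of the target column's observed cells, chosen
#' uniformly at random without replacement.  Exactly
#' `round(fraction * n_eligible)` cells become missing, reproducibly under
#' `seed`.
#'
#' @param x A [ResponseMatrix-class], matrix or data frame.
#' @param target Column (item) name to ampute.
#' @param fraction Proportion of eligible (observed) cells to remove, in
#'   (0, 1).
#' @param seed Integer seed controlling the random selection.
#' @return A list with elements `data` (the amputed object) and `mask`
#'   (a [MissingnessMask-class]).
#' @export
setGeneric("induceMCAR", function(x, target, fraction, seed)
  standardGeneric("induceMCAR"))

#' Induce missing-at-random missingness by sorted top-removal
#'
#' Sorts cases by a conditional variable (stably, ties broken by original
#' row order), removes the target value of the first
#' `round(fraction * n)` cases in that order, then restores the original
#' row order.  Missingness thereby depends on the observed conditional
#' variable only -- the MAR mechanism.
#'
#' @param x A [ResponseMatrix-class], matrix or data frame.
#' @param target Column (item) name to ampute.
#' @param conditional Column used to sort cases; must differ from `target`.
#' @param fraction Proportion of cases to ampute, in (0, 1).
#' @param direction `"descending"` (default: largest conditional values
#'   amputed first) or `"ascending"`.
#' @return A list with elements `data` and `mask` as for [induceMCAR()].
#' @export
setGeneric("induceMAR", function(x, target, conditional, fraction,
                                 direction = c("descending", "ascending"))
  standardGeneric("induceMAR"))

#' Little's test of the MCAR hypothesis
#'
#' Little's chi-square test compares the observed-variable means of each
#' missingness pattern with the grand means estimated by
#' expectation-maximization under multivariate normality.  A significant
#' statistic indicates a systematic relationship between missingness and
#' the data, i.e. departure from MCAR (expected under MAR).
#'
#' @param x A numeric matrix or data frame with `NA` for missing cells, or
#'   a [ResponseMatrix-class] (binary/ordinal items enter as integer codes,
#'   nominal items as K-1 level indicators).
#' @param columns Optional character vector restricting the test to a
#'   subset of columns.
#' @param tol,maxIter,ridge EM convergence tolerance, iteration cap, and
#'   ridge added to pattern covariance blocks for invertibility.
#' @return An object of classes `"littleTest"` and `"htest"` with the
#'   chi-square statistic, degrees of freedom, p-value and number of
#'   missingness patterns.  Complete data yield a degenerate result with
#'   `df = 0` and `p = 1`.
#' @export
setGeneric("littleMCARTest", function(x, columns = NULL, tol = 1e-8,
                                      maxIter = 200L, ridge = 1e-8)
  standardGeneric("littleMCARTest"))
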