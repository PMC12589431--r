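#' @include AllGenerics.R
#' @import methods
NULL

VALID_ROLES <- c("binary", "ordinal", "nominal", "continuous", "outcome", "ignore")
CATEGORICAL_ROLES <- c("binary", "ordinal", "nominal")

#' Variable specification
#'
#' Declares one column of a tabular dataset: its name, role, category
#' levels (for categorical roles) and the sentinel token marking missing
#' cells.  Level order is the coding order: the first level maps to
#' integer code 0.  For ordinal variables the order is meaningful; for
#' nominal variables it is arbitrary but fixed.
#'
#' @slot name Column name.
#' @slot role One of `"binary"`, `"ordinal"`, `"nominal"`, `"continuous"`,
#'   `"outcome"`, `"ignore"`.
#' @slot levels Character vector of category labels (empty for
#'   non-categorical roles).  Binary requires exactly 2; ordinal/nominal
#'   at least 2.
#' @slot missingSentinel Token recognized as missing (default `"-1"`; the
#'   empty string is always also treated as missing).
#' @seealso [variableSpec()], [datasetSchema()]
#' @export
setClass("VariableSpec",
  representation(name = "character", role = "character",
                 levels = "character", missingSentinel = "character"))

setValidity("VariableSpec", function(object) {
  msgs <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msgs <- c(msgs, "'name' must be a single non-empty string")
  if (length(object@role) != 1L || !object@role %in% VALID_ROLES)
    msgs <- c(msgs, sprintf("'role' must be one of: %s",
                            paste(VALID_ROLES, collapse = ", ")))
  if (length(object@role) == 1L && object@role %in% VALID_ROLES) {
    if (object@role == "binary" && length(object@levels) != 2L)
      msgs <- c(msgs, "binary variables require exactly 2 levels")
    if (object@role %in% c("ordinal", "nominal") && length(object@levels) < 2L)
      msgs <- c(msgs, sprintf("%s variables require at least 2 levels", object@role))
    if (!object@role %in% CATEGORICAL_ROLES && length(object@levels) > 0L)
      msgs <- c(msgs, sprintf("role '%s' must not declare levels", object@role))
  }
  if (anyDuplicated(object@levels))
    msgs <- c(msgs, "levels must be unique")
  if (length(object@missingSentinel) != 1L)
    msgs <- c(msgs, "'missingSentinel' must be a single string")
  if (length(msgs)) msgs else TRUE
})

#' Dataset schema
#'
#' A list of [VariableSpec-class] objects plus the name of the target
#' variable to be imputed and an optional conditional variable used for
#' MAR amputation.
#'
#' @slot variables List of [VariableSpec-class].
#' @slot target Name of the variable to impute; must have a categorical
#'   role.
#' @slot conditional Optional name of the MAR conditioning variable
#'   (`NA_character_` when unset); must differ from `target`.
#' @seealso [datasetSchema()], [readSchema()]
#' @export
setClass("DatasetSchema",
  representation(variables = "list", target = "character",
                 conditional = "character"))

setValidity("DatasetSchema", function(object) {
  msgs <- character()
  if (!all(vapply(object@variables, is, logical(1L), "VariableSpec")))
    return("'variables' must be a list of VariableSpec objects")
  nm <- vapply(object@variables, function(v) v@name, character(1L))
  if (anyDuplicated(nm))
    msgs <- c(msgs, "variable names must be unique")
  if (length(object@target) != 1L)
    msgs <- c(msgs, "'target' must be a single name")
  else if (!is.na(object@target)) {
    if (!object@target %in% nm)
      msgs <- c(msgs, sprintf("target '%s' is not a declared variable", object@target))
    else {
      role <- object@variables[[match(object@target, nm)]]@role
      if (!role %in% CATEGORICAL_ROLES)
        msgs <- c(msgs, "target must have role binary, ordinal or nominal")
    }
  }
  if (length(object@conditional) != 1L)
    msgs <- c(msgs, "'conditional' must be a single name or NA")
  else if (!is.na(object@conditional)) {
    if (!object@conditional %in% nm)
      msgs <- c(msgs, sprintf("conditional '%s' is not a declared variable",
                              object@conditional))
    if (identical(object@conditional, object@target))
      msgs <- c(msgs, "conditional must differ from target")
  }
  if (length(msgs)) msgs else TRUE
})

#' Integer-coded response matrix with observation mask
#'
#' The central data container: a cases-by-items matrix of integer category
#' codes (`0..K_i-1` per item) together with a logical observation mask of
#' the same shape.  Where the mask is `FALSE` the stored code carries no
#' information and is never read.  Non-item columns of the source table
#' (continuous, outcome) are carried alongside in `caseData` and are never
#' consulted by model fitting or imputation.
#'
#' @slot values Integer matrix, cases x items.
#' @slot observed Logical matrix, same shape; `TRUE` where the cell was
#'   observed.
#' @slot itemSpecs List of [VariableSpec-class], one per item column.
#' @slot caseData Data frame of non-item columns (possibly zero columns),
#'   one row per case.
#'
#' @section Accessors:
#' `responseValues(x)`, `observedMask(x)`, `itemSpecs(x)`, `caseData(x)`,
#' `itemNames(x)`, `nCases(x)`, `nItems(x)`, `dim(x)`.
#' @seealso [responseMatrix()], [readResponseTable()], [validateResponses()]
#' @aliases responseValues observedMask itemSpecs caseData itemNames nCases
#'   nItems
#' @export
setClass("ResponseMatrix",
  representation(values = "matrix", observed = "matrix",
                 itemSpecs = "list", caseData = "data.frame"))

setValidity("ResponseMatrix", function(object) {
  msgs <- character()
  if (!identical(dim(object@values), dim(object@observed)))
    msgs <- c(msgs, "'values' and 'observed' must have identical dimensions")
  if (!is.integer(object@values))
    msgs <- c(msgs, "'values' must be an integer matrix")
  if (!is.logical(object@observed) || anyNA(object@observed))
    msgs <- c(msgs, "'observed' must be a logical matrix without NA")
  if (length(object@itemSpecs) != ncol(object@values))
    msgs <- c(msgs, "one VariableSpec required per item column")
  if (!all(vapply(object@itemSpecs, is, logical(1L), "VariableSpec")))
    return(c(msgs, "'itemSpecs' must be a list of VariableSpec objects"))
  if (length(msgs)) return(msgs)
  roles <- vapply(object@itemSpecs, function(v) v@role, character(1L))
  if (!all(roles %in% CATEGORICAL_ROLES))
    msgs <- c(msgs, "item columns must have categorical roles")
  nm <- vapply(object@itemSpecs, function(v) v@name, character(1L))
  if (!identical(colnames(object@values), nm))
    msgs <- c(msgs, "column names of 'values' must match item spec names")
  if (nrow(object@caseData) != nrow(object@values) && ncol(object@caseData) > 0L)
    msgs <- c(msgs, "'caseData' must have one row per case")
  for (j in seq_along(object@itemSpecs)) {
    K <- length(object@itemSpecs[[j]]@levels)
    v <- object@values[, j][object@observed[, j]]
    if (anyNA(v) || (length(v) && (min(v) < 0L || max(v) >= K)))
      msgs <- c(msgs, sprintf("observed codes of item '%s' must lie in 0..%d",
                              nm[j], K - 1L))
  }
  if (length(msgs)) msgs else TRUE
})

#' Item classes for the three response models
#'
#' `TwoPLItem` holds the two-parameter logistic model for a binary item:
#' discrimination `a` and difficulty `b`.  `GRMItem` holds the graded
#' response model for an ordered item: a common discrimination `a` and
#' `K-1` non-decreasing thresholds.  `NRMItem` holds the nominal response
#' model: per-category slopes and intercepts with the first category fixed
#' at zero for identification.
#'
#' @slot name Item name (may be empty).
#' @slot a Discrimination (2PL, GRM).
#' @slot b Difficulty (2PL).
#' @slot thresholds Non-decreasing boundary locations `b_1..b_{K-1}` (GRM).
#' @slot slopes,intercepts Per-category parameters `a_1..a_K`,
#'   `c_1..c_K` with `a_1 = c_1 = 0` (NRM).
#' @seealso [twoPLItem()], [grmItem()], [nrmItem()], [categoryProbs()]
#' @aliases TwoPLItem-class GRMItem-class NRMItem-class
#' @name IRTItem-class
#' @export
setClass("IRTItem", representation("VIRTUAL", name = "character"))

#' @rdname IRTItem-class
#' @export
setClass("TwoPLItem", contains = "IRTItem",
  representation(a = "numeric", b = "numeric"))

setValidity("TwoPLItem", function(object) {
  if (length(object@a) != 1L || length(object@b) != 1L ||
      !is.finite(object@a) || !is.finite(object@b))
    "'a' and 'b' must be single finite numbers" else TRUE
})

#' @rdname IRTItem-class
#' @export
setClass("GRMItem", contains = "IRTItem",
  representation(a = "numeric", thresholds = "numeric"))

setValidity("GRMItem", function(object) {
  msgs <- character()
  if (length(object@a) != 1L || !is.finite(object@a))
    msgs <- c(msgs, "'a' must be a single finite number")
  if (length(object@thresholds) < 1L || !all(is.finite(object@thresholds)))
    msgs <- c(msgs, "'thresholds' must be finite and non-empty")
  else if (is.unsorted(object@thresholds))
    msgs <- c(msgs, "'thresholds' must be non-decreasing")
  if (length(msgs)) msgs else TRUE
})

#' @rdname IRTItem-class
#' @export
setClass("NRMItem", contains = "IRTItem",
  representation(slopes = "numeric", intercepts = "numeric"))

setValidity("NRMItem", function(object) {
  msgs <- character()
  if (length(object@slopes) < 2L ||
      length(object@slopes) != length(object@intercepts))
    msgs <- c(msgs, "'slopes' and 'intercepts' must have equal length >= 2")
  if (!all(is.finite(object@slopes)) || !all(is.finite(object@intercepts)))
    msgs <- c(msgs, "parameters must be finite")
  if (length(object@slopes) >= 1L &&
      (object@slopes[1L] != 0 || object@intercepts[1L] != 0))
    msgs <- c(msgs, "identification requires slopes[1] == intercepts[1] == 0")
  if (length(msgs)) msgs else TRUE
})

#' Quadrature grid over the latent trait
#'
#' Fixed integration grid used by marginal maximum likelihood and EAP
#' scoring: strictly increasing nodes with standard-normal prior weights
#' renormalized to sum to 1.
#'
#' @slot nodes Strictly increasing numeric vector of latent-trait points.
#' @slot weights Non-negative weights summing to 1.
#' @seealso [buildQuadrature()]
#' @export
setClass("Quadrature",
  representation(nodes = "numeric", weights = "numeric"))

setValidity("Quadrature", function(object) {
  msgs <- character()
  if (length(object@nodes) != length(object@weights))
    msgs <- c(msgs, "nodes and weights must have equal length")
  if (is.unsorted(object@nodes, strictly = TRUE))
    msgs <- c(msgs, "nodes must be strictly increasing")
  if (any(object@weights < 0) || abs(sum(object@weights) - 1) > 1e-12)
    msgs <- c(msgs, "weights must be non-negative and sum to 1 within 1e-12")
  if (length(msgs)) msgs else TRUE
})

#' Fitted marginal maximum likelihood model
#'
#' Result of [fitIRT()]: the estimated item objects, the quadrature grid,
#' the final marginal log-likelihood, the per-iteration log-likelihood
#' trace (non-decreasing, an EM guarantee), and convergence information.
#'
#' @slot items List of fitted item objects aligned with the response
#'   matrix's item columns.
#' @slot itemSpecs The item [VariableSpec-class] list the model was fitted
#'   to (levels possibly collapsed, see [fitIRT()]).
#' @slot quadrature [Quadrature-class] used for integration.
#' @slot loglik Final marginal log-likelihood.
#' @slot trace Per-iteration marginal log-likelihood.
#' @slot converged Logical convergence flag.
#' @slot nIter Number of EM iterations performed.
#' @slot control The control list used (see [irtControl()]).
#' @seealso [fitIRT()], [eapTheta()], [imputeDataset()]
#' @export
setClass("IRTFit",
  representation(items = "list", itemSpecs = "list",
                 quadrature = "Quadrature", loglik = "numeric",
                 trace = "numeric", converged = "logical",
                 nIter = "integer", control = "list"))

setValidity("IRTFit", function(object) {
  msgs <- character()
  if (!all(vapply(object@items, is, logical(1L), "IRTItem")))
    msgs <- c(msgs, "'items' must be a list of IRTItem objects")
  if (length(object@items) != length(object@itemSpecs))
    msgs <- c(msgs, "'items' and 'itemSpecs' must align")
  if (length(object@trace) &&
      any(diff(object@trace) < -1e-8))
    msgs <- c(msgs, "log-likelihood trace must be non-decreasing (tol 1e-8)")
  if (length(msgs)) msgs else TRUE
})

#' Record of a single-column amputation
#'
#' Describes which cells of the target column were made missing by
#' [induceMCAR()] or [induceMAR()], the mechanism, the fraction, and the
#' mechanism's own parameters (seed, or conditional variable + direction).
#'
#' @slot target Amputed column name.
#' @slot cases Integer indices of newly-missing cases.
#' @slot mechanism `"MCAR"` or `"MAR"`.
#' @slot fraction Requested missing fraction.
#' @slot details List: `seed` for MCAR; `conditional` and `direction` for
#'   MAR.
#' @export
setClass("MissingnessMask",
  representation(target = "character", cases = "integer",
                 mechanism = "character", fraction = "numeric",
                 details = "list"))

setValidity("MissingnessMask", function(object) {
  msgs <- character()
  if (!object@mechanism %in% c("MCAR", "MAR"))
    msgs <- c(msgs, "mechanism must be MCAR or MAR")
  if (object@fraction <= 0 || object@fraction >= 1)
    msgs <- c(msgs, "fraction must lie in (0, 1)")
  if (anyDuplicated(object@cases))
    msgs <- c(msgs, "case indices must be unique")
  if (length(msgs)) msgs else TRUE
})

#' Imputation report
#'
#' Result of [imputeDataset()]: for every case whose target cell was
#' missing, the imputed category code, the full model-implied category
#' probability vector at the case's EAP trait score, and the trait
#' estimate itself.  Cases with no observed responses at all are scored at
#' the prior mean and flagged.
#'
#' @slot target Target item name.
#' @slot cases Integer indices of the imputed cases.
#' @slot values Integer imputed codes (within the target's level set).
#' @slot probs Matrix of category probabilities, one row per imputed case;
#'   rows sum to 1.
#' @slot theta Data frame of `eap`, `psd`, `nObserved` for the imputed
#'   cases.
#' @slot priorOnly Logical flag per imputed case: `TRUE` when the case had
#'   zero observed items and was scored from the prior alone.
#' @seealso [imputeDataset()], [applyImputation()]
#' @export
setClass("ImputationReport",
  representation(target = "character", cases = "integer",
                 values = "integer", probs = "matrix",
                 theta = "data.frame", priorOnly = "logical"))

setValidity("ImputationReport", function(object) {
  msgs <- character()
  n <- length(object@cases)
  if (length(object@values) != n || nrow(object@probs) != n ||
      nrow(object@theta) != n || length(object@priorOnly) != n)
    msgs <- c(msgs, "all per-case slots must have one entry per imputed case")
  if (n && any(abs(rowSums(object@probs) - 1) > 1e-12))
    msgs <- c(msgs, "probability rows must sum to 1 within 1e-12")
  if (n && (min(object@values) < 0L || max(object@values) >= ncol(object@probs)))
    msgs <- c(msgs, "imputed codes must lie within the target's level set")
  if (length(msgs)) msgs else TRUE
})

#' Item bank
#'
#' A named collection of item objects with matching variable
#' specifications, used to generate synthetic response data and as the
#' ground truth in recovery studies.
#'
#' @slot items List of [IRTItem-class] objects.
#' @slot specs List of [VariableSpec-class], one per item, giving names,
#'   roles and level labels.
#' @seealso [itemBank()], [simulateResponses()]
#' @export
setClass("ItemBank", representation(items = "list", specs = "list"))

setValidity("ItemBank", function(object) {
  msgs <- character()
  if (length(object@items) != length(object@specs))
    return("'items' and 'specs' must have equal length")
  if (!all(vapply(object@items, is, logical(1L), "IRTItem")) ||
      !all(vapply(object@specs, is, logical(1L), "VariableSpec")))
    return("bank must hold IRTItem and VariableSpec objects")
  for (j in seq_along(object@items)) {
    if (nCategories(object@items[[j]]) != length(object@specs[[j]]@levels))
      msgs <- c(msgs, sprintf("item %d: category count disagrees with levels", j))
  }
  nm <- vapply(object@specs, function(v) v@name, character(1L))
  if (anyDuplicated(nm)) msgs <- c(msgs, "item names must be unique")
  if (length(msgs)) msgs else TRUE
})

#' Benchmark simulation configuration
#'
#' Declares one synthetic benchmark: the number of cases, the generating
#' item bank, the target and MAR-conditional items, the missing fractions
#' and mechanisms of the amputation grid, and the master seed.  The
#' default grid (2 mechanisms x 4 fractions) yields eight amputed variants
#' of one complete dataset.
#'
#' @slot n Number of cases.
#' @slot bank Generating [ItemBank-class].
#' @slot target Item to ampute and impute.
#' @slot conditional Item used to induce MAR missingness.
#' @slot fractions Missing fractions (default 0.05, 0.10, 0.30, 0.50).
#' @slot mechanisms Mechanisms (default MCAR and MAR).
#' @slot seed Master seed.
#' @seealso [simulationConfig()], [makeBenchmark()], [benchmarkPreset()]
#' @export
setClass("SimulationConfig",
  representation(n = "integer", bank = "ItemBank", target = "character",
                 conditional = "character", fractions = "numeric",
                 mechanisms = "character", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  nm <- vapply(object@bank@specs, function(v) v@name, character(1L))
  if (!object@target %in% nm)
    msgs <- c(msgs, "target must be an item of the bank")
  if (!is.na(object@conditional) && !object@conditional %in% nm)
    msgs <- c(msgs, "conditional must be an item of the bank")
  if (identical(object@conditional, object@target))
    msgs <- c(msgs, "conditional must differ from target")
  if (any(object@fractions <= 0) || any(object@fractions >= 1))
    msgs <- c(msgs, "fractions must lie in (0, 1)")
  if (!all(object@mechanisms %in% c("MCAR", "MAR")))
    msgs <- c(msgs, "mechanisms must be MCAR and/or MAR")
  if (object@n < 1L) msgs <- c(msgs, "n must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Quartile (quantile) discretization of a continuous column
#'
#' Records the cut points that map a continuous feature onto ordinal codes
#' `0..nBins-1`: bins are left-closed/right-open at the empirical
#' `i/nBins` quantiles, the last bin closed.
#'
#' @slot column Source column name.
#' @slot cuts Strictly increasing interior cut points (length `nBins - 1`).
#' @slot nBins Number of bins produced (default 4: quartiles).
#' @seealso [quartileDiscretize()]
#' @export
setClass("Discretization",
  representation(column = "character", cuts = "numeric", nBins = "integer"))

setValidity("Discretization", function(object) {
  msgs <- character()
  if (length(object@cuts) != object@nBins - 1L)
    msgs <- c(msgs, "need nBins - 1 cut points")
  if (length(object@cuts) > 1L && is.unsorted(object@cuts, strictly = TRUE))
    msgs <- c(msgs, "cut points must be strictly increasing")
  if (length(msgs)) msgs else TRUE
})
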