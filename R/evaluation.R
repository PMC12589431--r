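#' @include response-matrix.R
NULL

#' Quantile discretization of a continuous column
#'
#' Cuts a continuous feature at its empirical `i/nBins` quantiles into
#' `nBins` ordinal codes `0..nBins-1` (default 4: quartiles).  Bins are
#' left-closed/right-open at the cut points, the last bin closed, so the
#' bin counts are equal up to quantile ties.  This is the recoding applied
#' to continuous features before an IRT run -- item response models take
#' categorical responses -- and is never applied to saved imputed output.
#'
#' @param values Numeric vector with at least `nBins` distinct values.
#' @param nBins Number of bins (default 4).
#' @param column Optional source column name recorded in the result.
#' @return A list with `codes` (integer vector, `NA` where `values` is
#'   `NA`) and `discretization` (a [Discretization-class]).
#' @examples
#' quartileDiscretize(1:8)$codes  # 0 0 1 1 2 2 3 3
#' @export
quartileDiscretize <- function(values, nBins = 4L, column = "") {
  nBins <- as.integer(nBins)
  stopIfNot(nBins >= 2L, "'nBins' must be at least 2")
  obs <- values[!is.na(values)]
  stopIfNot(length(unique(obs)) >= nBins,
            "fewer than %d distinct values; use fewer bins", nBins)
  cuts <- unname(stats::quantile(obs, probs = seq_len(nBins - 1L) / nBins,
                                 names = FALSE))
  stopIfNot(!anyDuplicated(cuts),
            "tied quantiles produce duplicate cut points; use fewer bins")
  codes <- findInterval(values, cuts)
  codes[is.na(values)] <- NA_integer_
  list(codes = as.integer(codes),
       discretization = new("Discretization", column = column, cuts = cuts,
                            nBins = nBins))
}

#' Move a continuous case-data column into the item set
#'
#' Applies [quartileDiscretize()] to a numeric `caseData` column and
#' appends the result as an ordinal item, so the column can enter an IRT
#' fit.  The original continuous column is retained in `caseData`; the
#' conversion only affects the item set used for model fitting.
#'
#' @param x A [ResponseMatrix-class].
#' @param column Name of the numeric `caseData` column.
#' @param nBins Number of bins (default 4).
#' @param name Name of the new ordinal item (default `column` with a
#'   `".q"` suffix).
#' @return A list with the augmented [ResponseMatrix-class] (`data`) and
#'   the [Discretization-class] used (`discretization`).
#' @export
discretizeItems <- function(x, column, nBins = 4L,
                            name = paste0(column, ".q")) {
  stopIfNot(column %in% colnames(x@caseData),
            "'%s' is not a caseData column", column)
  qd <- quartileDiscretize(x@caseData[[column]], nBins, column = column)
  newSpec <- variableSpec(name, "ordinal",
                          levels = as.character(seq_len(nBins) - 1L))
  values <- cbind(x@values, qd$codes)
  observed <- cbind(x@observed, !is.na(qd$codes))
  list(data = responseMatrix(values, observed, c(x@itemSpecs, newSpec),
                             x@caseData),
       discretization = qd$discretization)
}

#' F1 score of imputed cells against ground truth
#'
#' Per-class one-vs-rest precision, recall and F1
#' (`F1 = 2 * precision * recall / (precision + recall)`, with 0/0
#' defined as 0), computed over the amputed-and-imputed cells only, plus
#' an aggregate.  Averaging modes: `"weighted"` (default; class
#' frequencies in the truth), `"macro"` (unweighted mean), `"micro"`
#' (pooled counts -- overall accuracy for single-label data), and
#' `"binary"` (the positive class's own F1).
#'
#' @param truth Integer/factor vector of true codes at the masked cells.
#' @param imputed Vector of imputed codes, same length.
#' @param averaging Aggregation mode.
#' @param positive Positive class for `averaging = "binary"` (default:
#'   the highest class).
#' @param levels Optional explicit class set; defaults to the classes
#'   present in `truth` or `imputed`.
#' @return A list of class `"f1Report"`: `perClass` data frame
#'   (class, n, precision, recall, f1), `aggregate`, `averaging`,
#'   `confusion` table.
#' @examples
#' imputationF1(c(0, 1, 1, 0), c(0, 1, 0, 0))$aggregate
#' @export
imputationF1 <- function(truth, imputed,
                         averaging = c("weighted", "macro", "micro", "binary"),
                         positive = NULL, levels = NULL) {
  averaging <- match.arg(averaging)
  stopIfNot(length(truth) == length(imputed),
            "'truth' and 'imputed' must have equal length")
  stopIfNot(length(truth) > 0L, "no imputed cells to score")
  if (is.null(levels)) levels <- sort(unique(c(truth, imputed)))
  truth <- factor(truth, levels = levels)
  imputed <- factor(imputed, levels = levels)
  stopIfNot(!anyNA(truth) && !anyNA(imputed),
            "codes outside the declared level set")
  conf <- table(truth = truth, imputed = imputed)
  tp <- diag(conf)
  prec <- ifelse(colSums(conf) > 0, tp / colSums(conf), 0)
  rec <- ifelse(rowSums(conf) > 0, tp / rowSums(conf), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  perClass <- data.frame(class = as.character(levels),
                         n = as.integer(rowSums(conf)),
                         precision = as.numeric(prec),
                         recall = as.numeric(rec), f1 = as.numeric(f1))
  aggregate <- switch(averaging,
    weighted = sum(perClass$n * perClass$f1) / sum(perClass$n),
    macro = mean(perClass$f1),
    micro = sum(tp) / sum(conf),
    binary = {
      pos <- if (is.null(positive)) levels[length(levels)] else positive
      stopIfNot(as.character(pos) %in% as.character(levels),
                "positive class not among the levels")
      perClass$f1[match(as.character(pos), perClass$class)]
    })
  structure(list(perClass = perClass, aggregate = aggregate,
                 averaging = averaging, confusion = conf),
            class = "f1Report")
}

#' @export
print.f1Report <- function(x, ...) {
  cat(sprintf("F1 over %d imputed cell(s): %.4f (%s averaging)\n",
              sum(x$perClass$n), x$aggregate, x$averaging))
  print(x$perClass, row.names = FALSE)
  invisible(x)
}

#' Modal-category baseline imputation
#'
#' Imputes every missing cell with the most frequent observed category of
#' the target item -- the floor any informative imputer must beat.  Ties
#' resolve to the lowest category code.
#'
#' @param x A [ResponseMatrix-class] (the amputed data).
#' @param target Target item name.
#' @return Integer vector: the modal code repeated for every missing cell
#'   of the target, named by case index.
#' @export
modalBaseline <- function(x, target) {
  j <- itemIndex(x, target)
  v <- x@values[x@observed[, j], j]
  stopIfNot(length(v) > 0L, "target has no observed cells")
  tab <- tabulate(v + 1L, nbins = length(x@itemSpecs[[j]]@levels))
  mode <- which.max(tab) - 1L
  cases <- which(!x@observed[, j])
  stats::setNames(rep(as.integer(mode), length(cases)), cases)
}

#' Score an imputation report against the pre-amputation truth
#'
#' Convenience wrapper: extracts the true codes of the masked cells from
#' the complete matrix and the imputed codes from the report, and
#' computes [imputationF1()].
#'
#' @param report An [ImputationReport-class] (or a named integer vector of
#'   imputed codes, e.g. from [modalBaseline()]).
#' @param truth The complete [ResponseMatrix-class] before amputation.
#' @param target Target item name.
#' @param ... Passed to [imputationF1()].
#' @return An `"f1Report"` list.
#' @export
scoreImputation <- function(report, truth, target, ...) {
  j <- itemIndex(truth, target)
  if (is(report, "ImputationReport")) {
    cases <- report@cases
    imputed <- report@values
  } else {
    cases <- as.integer(names(report))
    imputed <- as.integer(report)
  }
  K <- length(truth@itemSpecs[[j]]@levels)
  imputationF1(truth@values[cases, j], imputed,
               levels = seq_len(K) - 1L, ...)
}
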