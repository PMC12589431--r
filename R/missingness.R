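#' @include response-matrix.R
NULL

newMask <- function(target, cases, mechanism, fraction, details)
  new("MissingnessMask", target = target, cases = as.integer(cases),
      mechanism = mechanism, fraction = fraction, details = details)

#' @describeIn induceMCAR Case indices recorded in a mask.
#' @param mask A [MissingnessMask-class].
#' @export
maskedCases <- function(mask) mask@cases

setMethod("show", "MissingnessMask", function(object)
  cat(sprintf("MissingnessMask: %s, %d cell(s) of '%s' (fraction %.3g)\n",
              object@mechanism, length(object@cases), object@target,
              object@fraction)))

mcarPick <- function(eligible, fraction, seed) {
  stopIfNot(length(fraction) == 1L && fraction > 0 && fraction < 1,
            "'fraction' must lie in (0, 1)")
  k <- round(fraction * length(eligible))
  withSeed(seed, sort(sample(eligible, k)))
}

marPick <- function(condValues, targetObserved, fraction, direction) {
  stopIfNot(length(fraction) == 1L && fraction > 0 && fraction < 1,
            "'fraction' must lie in (0, 1)")
  stopIfNot(!all(is.na(condValues)), "conditional column is entirely missing")
  n <- length(condValues)
  ord <- order(if (direction == "descending") -xtfrm(condValues)
               else xtfrm(condValues),
               seq_len(n), na.last = TRUE)
  k <- round(fraction * n)
  picked <- ord[targetObserved[ord]][seq_len(min(k, sum(targetObserved)))]
  sort(picked)
}

#' @rdname induceMCAR
#' @export
setMethod("induceMCAR", "ResponseMatrix",
  function(x, target, fraction, seed) {
    j <- itemIndex(x, target)
    eligible <- which(x@observed[, j])
    cases <- mcarPick(eligible, fraction, seed)
    observed <- x@observed
    observed[cases, j] <- FALSE
    out <- responseMatrix(x@values, observed, x@itemSpecs, x@caseData)
    list(data = out,
         mask = newMask(target, cases, "MCAR", fraction, list(seed = seed)))
  })

#' @rdname induceMCAR
#' @export
setMethod("induceMCAR", "data.frame",
  function(x, target, fraction, seed) {
    stopIfNot(target %in% colnames(x), "target '%s' not found", target)
    eligible <- which(!is.na(x[[target]]))
    cases <- mcarPick(eligible, fraction, seed)
    x[cases, target] <- NA
    list(data = x,
         mask = newMask(target, cases, "MCAR", fraction, list(seed = seed)))
  })

#' @rdname induceMCAR
#' @export
setMethod("induceMCAR", "matrix",
  function(x, target, fraction, seed) {
    res <- induceMCAR(as.data.frame(x), target, fraction, seed)
    res$data <- as.matrix(res$data)
    res
  })

#' @rdname induceMAR
#' @export
setMethod("induceMAR", "ResponseMatrix",
  function(x, target, conditional, fraction,
           direction = c("descending", "ascending")) {
    direction <- match.arg(direction)
    stopIfNot(!identical(conditional, target),
              "conditional must differ from target")
    j <- itemIndex(x, target)
    cond <- if (conditional %in% itemNames(x)) {
      jc <- itemIndex(x, conditional)
      cv <- x@values[, jc]
      cv[!x@observed[, jc]] <- NA_integer_
      cv
    } else if (conditional %in% colnames(x@caseData)) {
      x@caseData[[conditional]]
    } else stop(sprintf("conditional '%s' not found", conditional),
                call. = FALSE)
    cases <- marPick(cond, x@observed[, j], fraction, direction)
    observed <- x@observed
    observed[cases, j] <- FALSE
    out <- responseMatrix(x@values, observed, x@itemSpecs, x@caseData)
    list(data = out,
         mask = newMask(target, cases, "MAR", fraction,
                        list(conditional = conditional,
                             direction = direction)))
  })

#' @rdname induceMAR
#' @export
setMethod("induceMAR", "data.frame",
  function(x, target, conditional, fraction,
           direction = c("descending", "ascending")) {
    direction <- match.arg(direction)
    stopIfNot(target %in% colnames(x), "target '%s' not found", target)
    stopIfNot(conditional %in% colnames(x), "conditional '%s' not found",
              conditional)
    stopIfNot(!identical(conditional, target),
              "conditional must differ from target")
    cases <- marPick(x[[conditional]], !is.na(x[[target]]), fraction,
                     direction)
    x[cases, target] <- NA
    list(data = x,
         mask = newMask(target, cases, "MAR", fraction,
                        list(conditional = conditional,
                             direction = direction)))
  })

#' @rdname induceMAR
#' @export
setMethod("induceMAR", "matrix",
  function(x, target, conditional, fraction,
           direction = c("descending", "ascending")) {
    res <- induceMAR(as.data.frame(x), target, conditional, fraction,
                     direction)
    res$data <- as.matrix(res$data)
    res
  })

#' Restore amputed cells from the pre-amputation matrix
#'
#' Inverse of amputation: copies the masked cells' original values and
#' observation flags back, reproducing the pre-amputation matrix exactly.
#'
#' @param amputed The amputed [ResponseMatrix-class].
#' @param original The matrix before amputation.
#' @param mask The [MissingnessMask-class] produced by the amputation.
#' @return A [ResponseMatrix-class] equal to `original`.
#' @export
restoreMask <- function(amputed, original, mask) {
  j <- itemIndex(amputed, mask@target)
  values <- amputed@values; observed <- amputed@observed
  values[mask@cases, j] <- original@values[mask@cases, j]
  observed[mask@cases, j] <- original@observed[mask@cases, j]
  responseMatrix(values, observed, amputed@itemSpecs, amputed@caseData)
}
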