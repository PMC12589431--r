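#' @include AllClasses.R
NULL

#' Item constructors
#'
#' Build item objects for the three response models.  `twoPLItem(a, b)` is
#' the two-parameter logistic model for a binary item; `grmItem(a,
#' thresholds)` the graded response model with a common slope and
#' non-decreasing boundary locations; `nrmItem(slopes, intercepts)` the
#' nominal response model, identified by fixing the first category's slope
#' and intercept at zero.
#'
#' @param a Discrimination parameter.
#' @param b Difficulty (2PL).
#' @param thresholds Non-decreasing boundary locations (GRM), length
#'   `K - 1`.
#' @param slopes,intercepts Per-category parameters (NRM), length `K`,
#'   first entries 0.
#' @param name Optional item name.
#' @return An object of class [TwoPLItem-class], [GRMItem-class] or
#'   [NRMItem-class].
#' @examples
#' categoryProbs(twoPLItem(1.5, 0.5), theta = c(-1, 0, 1))
#' grmCategoryProbs(0, grmItem(1, c(-1, 0, 1)))
#' @name itemConstructors
NULL

#' @rdname itemConstructors
#' @export
twoPLItem <- function(a, b, name = "") {
  new("TwoPLItem", a = as.numeric(a), b = as.numeric(b), name = name)
}

#' @rdname itemConstructors
#' @export
grmItem <- function(a, thresholds, name = "") {
  new("GRMItem", a = as.numeric(a), thresholds = as.numeric(thresholds),
      name = name)
}

#' @rdname itemConstructors
#' @export
nrmItem <- function(slopes, intercepts, name = "") {
  new("NRMItem", slopes = as.numeric(slopes),
      intercepts = as.numeric(intercepts), name = name)
}

#' Two-parameter logistic response probability
#'
#' Probability of the positive response under the 2PL model,
#' `exp(a (theta - b)) / (1 + exp(a (theta - b)))`, evaluated
#' overflow-safely.  The logistic metric is used throughout (no `D = 1.7`
#' scaling constant).
#'
#' @param theta Numeric vector of latent-trait values.
#' @param a Discrimination.
#' @param b Difficulty.
#' @return Probabilities in `(0, 1)` (for finite arguments of moderate
#'   magnitude; extreme arguments saturate at the nearest representable
#'   value).
#' @examples
#' prob2PL(0, a = 2, b = 0)   # 0.5 at theta == b
#' @export
prob2PL <- function(theta, a, b) {
  stopIfNot(all(is.finite(theta)) && all(is.finite(a)) && all(is.finite(b)),
            "prob2PL requires finite inputs")
  stats::plogis(a * (theta - b))
}

#' Graded-response boundary probabilities
#'
#' The GRM builds an ordered item from `K - 1` cumulative 2PL curves: the
#' k-th boundary probability is the probability of responding in category
#' k or above, `prob2PL(theta, a, b_k)`.  For a positive slope the
#' boundary vector is non-increasing in k.
#'
#' @param theta Numeric vector of latent-trait values.
#' @param item A [GRMItem-class].
#' @return Matrix of boundary probabilities, `length(theta)` rows and
#'   `K - 1` columns.
#' @export
grmBoundaryProbs <- function(theta, item) {
  stopIfNot(is(item, "GRMItem"), "'item' must be a GRMItem")
  stopIfNot(!is.unsorted(item@thresholds), "GRM thresholds must be sorted")
  stopIfNot(all(is.finite(theta)), "theta must be finite")
  bp <- vapply(item@thresholds, function(b) stats::plogis(item@a * (theta - b)),
               numeric(length(theta)))
  if (!is.matrix(bp)) bp <- matrix(bp, nrow = length(theta))
  bp
}

#' Graded-response category probabilities
#'
#' Adjacent differences of the boundary curves: the probability of
#' responding at the lowest category or above is 1, above the highest
#' category is 0, and category k's probability is
#' `P*_k(theta) - P*_{k+1}(theta)`.
#'
#' @inheritParams grmBoundaryProbs
#' @return Matrix of category probabilities (`length(theta)` x `K`); rows
#'   sum to 1.
#' @export
grmCategoryProbs <- function(theta, item) {
  bp <- grmBoundaryProbs(theta, item)
  cum <- cbind(1, bp, 0)
  out <- cum[, -ncol(cum), drop = FALSE] - cum[, -1L, drop = FALSE]
  pmax(out, 0)
}

#' Nominal-response category probabilities
#'
#' Divide-by-total (softmax) model: category j's probability is
#' `exp(a_j theta + c_j)` divided by the sum over all categories,
#' computed with max-subtraction for numerical stability.  The first
#' category's slope and intercept are fixed at zero for identification.
#'
#' @param theta Numeric vector of latent-trait values.
#' @param item An [NRMItem-class].
#' @return Matrix of category probabilities (`length(theta)` x `K`); rows
#'   sum to 1.
#' @export
nrmCategoryProbs <- function(theta, item) {
  stopIfNot(is(item, "NRMItem"), "'item' must be an NRMItem")
  stopIfNot(item@slopes[1L] == 0 && item@intercepts[1L] == 0,
            "NRM identification constraint violated: first category not zero")
  stopIfNot(all(is.finite(theta)), "theta must be finite")
  z <- outer(theta, item@slopes) +
    matrix(item@intercepts, length(theta), length(item@slopes), byrow = TRUE)
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' @rdname categoryProbs
#' @export
setMethod("categoryProbs", "TwoPLItem", function(item, theta) {
  p <- prob2PL(theta, item@a, item@b)
  cbind(1 - p, p)
})

#' @rdname categoryProbs
#' @export
setMethod("categoryProbs", "GRMItem", function(item, theta)
  grmCategoryProbs(theta, item))

#' @rdname categoryProbs
#' @export
setMethod("categoryProbs", "NRMItem", function(item, theta)
  nrmCategoryProbs(theta, item))

#' @rdname nCategories
#' @export
setMethod("nCategories", "TwoPLItem", function(x) 2L)

#' @rdname nCategories
#' @export
setMethod("nCategories", "GRMItem", function(x) length(x@thresholds) + 1L)

#' @rdname nCategories
#' @export
setMethod("nCategories", "NRMItem", function(x) length(x@slopes))

#' @rdname itemFamily
#' @export
setMethod("itemFamily", "TwoPLItem", function(x) "2PL")

#' @rdname itemFamily
#' @export
setMethod("itemFamily", "GRMItem", function(x) "GRM")

#' @rdname itemFamily
#' @export
setMethod("itemFamily", "NRMItem", function(x) "NRM")

setMethod("show", "TwoPLItem", function(object)
  cat(sprintf("2PL item%s: a = %.4g, b = %.4g\n",
              if (nzchar(object@name)) paste0(" '", object@name, "'") else "",
              object@a, object@b)))

setMethod("show", "GRMItem", function(object)
  cat(sprintf("GRM item%s (%d categories): a = %.4g, thresholds = %s\n",
              if (nzchar(object@name)) paste0(" '", object@name, "'") else "",
              nCategories(object), object@a,
              paste(sprintf("%.4g", object@thresholds), collapse = ", "))))

setMethod("show", "NRMItem", function(object)
  cat(sprintf("NRM item%s (%d categories): slopes = %s; intercepts = %s\n",
              if (nzchar(object@name)) paste0(" '", object@name, "'") else "",
              nCategories(object),
              paste(sprintf("%.4g", object@slopes), collapse = ", "),
              paste(sprintf("%.4g", object@intercepts), collapse = ", "))))

#' Read or write an item bank configuration file
#'
#' Item banks are stored as YAML: one entry per item with fields `name`,
#' `family` (`2PL`/`GRM`/`NRM`), the family's parameters, and the
#' category `levels`.
#'
#' @param path File path.
#' @return `readItemBank` returns an [ItemBank-class]; `writeItemBank`
#'   returns `path` invisibly.
#' @export
readItemBank <- function(path) {
  cfg <- yaml::read_yaml(path)
  items <- list(); specs <- list()
  for (e in cfg$items) {
    item <- switch(e$family,
      "2PL" = twoPLItem(e$a, e$b, name = e$name),
      "GRM" = grmItem(e$a, unlist(e$thresholds), name = e$name),
      "NRM" = nrmItem(unlist(e$slopes), unlist(e$intercepts), name = e$name),
      stop(sprintf("unknown item family '%s'", e$family), call. = FALSE))
    items[[length(items) + 1L]] <- item
    lv <- if (is.null(e$levels)) as.character(seq_len(nCategories(item)) - 1L)
          else as.character(unlist(e$levels))
    role <- switch(e$family, "2PL" = "binary", "GRM" = "ordinal", "NRM" = "nominal")
    specs[[length(specs) + 1L]] <- variableSpec(e$name, role, levels = lv)
  }
  new("ItemBank", items = items, specs = specs)
}

#' @rdname readItemBank
#' @param bank An [ItemBank-class] to serialize.
#' @export
writeItemBank <- function(bank, path) {
  stopIfNot(is(bank, "ItemBank"), "'bank' must be an ItemBank")
  entries <- lapply(seq_along(bank@items), function(j) {
    it <- bank@items[[j]]; sp <- bank@specs[[j]]
    e <- list(name = sp@name, family = itemFamily(it))
    if (is(it, "TwoPLItem")) { e$a <- it@a; e$b <- it@b }
    if (is(it, "GRMItem")) { e$a <- it@a; e$thresholds <- as.list(it@thresholds) }
    if (is(it, "NRMItem")) {
      e$slopes <- as.list(it@slopes); e$intercepts <- as.list(it@intercepts)
    }
    e$levels <- as.list(sp@levels)
    e
  })
  yaml::write_yaml(list(items = entries), path, precision = 12L)
  invisible(path)
}

#' Assemble an item bank
#'
#' @param items List of item objects with non-empty names.
#' @param levels Optional named list overriding the default category
#'   labels (`"0"`, `"1"`, ...) of individual items.
#' @return An [ItemBank-class].
#' @export
itemBank <- function(items, levels = list()) {
  specs <- lapply(items, function(it) {
    stopIfNot(nzchar(it@name), "every bank item needs a name")
    lv <- if (!is.null(levels[[it@name]])) as.character(levels[[it@name]])
          else as.character(seq_len(nCategories(it)) - 1L)
    role <- switch(itemFamily(it), "2PL" = "binary", "GRM" = "ordinal",
                   "NRM" = "nominal")
    variableSpec(it@name, role, levels = lv)
  })
  new("ItemBank", items = items, specs = specs)
}

setMethod("show", "ItemBank", function(object) {
  cat(sprintf("ItemBank: %d items\n", length(object@items)))
  for (it in object@items) show(it)
})
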