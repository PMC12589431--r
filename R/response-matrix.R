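#' @include AllClasses.R
NULL

#' Construct a response matrix
#'
#' @param values Integer matrix of category codes (`0..K_i-1` per item);
#'   cells marked unobserved may hold any code (ignored) or `NA`.
#' @param observed Logical matrix of the same shape; defaults to
#'   `!is.na(values)`.
#' @param itemSpecs List of [VariableSpec-class] objects, one per column,
#'   with categorical roles.
#' @param caseData Optional data frame of non-item columns (continuous
#'   features, outcomes) carried alongside the items.
#' @return A [ResponseMatrix-class] object.
#' @export
responseMatrix <- function(values, observed = NULL, itemSpecs,
                           caseData = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (is.null(observed)) observed <- !is.na(values)
  observed <- as.matrix(observed)
  if (is(itemSpecs, "VariableSpec")) itemSpecs <- list(itemSpecs)
  colnames(values) <- specNames(itemSpecs)
  colnames(observed) <- colnames(values)
  if (is.null(caseData)) caseData <- data.frame()[seq_len(nrow(values)), ,
                                                 drop = FALSE]
  values[!observed] <- NA_integer_
  new("ResponseMatrix", values = values, observed = observed,
      itemSpecs = itemSpecs, caseData = caseData)
}

#' @rdname ResponseMatrix-class
#' @param x A [ResponseMatrix-class].
#' @export
setMethod("responseValues", "ResponseMatrix", function(x) x@values)

#' @rdname ResponseMatrix-class
#' @export
setMethod("observedMask", "ResponseMatrix", function(x) x@observed)

#' @rdname ResponseMatrix-class
#' @export
setMethod("itemSpecs", "ResponseMatrix", function(x) x@itemSpecs)

#' @rdname ResponseMatrix-class
#' @export
setMethod("caseData", "ResponseMatrix", function(x) x@caseData)

#' @rdname ResponseMatrix-class
#' @export
setMethod("itemNames", "ResponseMatrix", function(x) specNames(x@itemSpecs))

#' @rdname ResponseMatrix-class
#' @export
setMethod("nCases", "ResponseMatrix", function(x) nrow(x@values))

#' @rdname ResponseMatrix-class
#' @export
setMethod("nItems", "ResponseMatrix", function(x) ncol(x@values))

#' @rdname ResponseMatrix-class
#' @export
setMethod("dim", "ResponseMatrix", function(x) dim(x@values))

setMethod("show", "ResponseMatrix", function(object) {
  nm <- sum(!object@observed)
  cat(sprintf("ResponseMatrix: %d cases x %d items (%d unobserved cells, %.1f%%)\n",
              nrow(object@values), ncol(object@values), nm,
              100 * nm / max(1L, length(object@values))))
  roles <- specRoles(object@itemSpecs)
  cat(sprintf("items: %s\n",
              paste(sprintf("%s(%s)", itemNames(object), roles), collapse = ", ")))
  if (ncol(object@caseData))
    cat(sprintf("case data: %s\n",
                paste(colnames(object@caseData), collapse = ", ")))
})

itemIndex <- function(x, item) {
  j <- match(item, itemNames(x))
  stopIfNot(!is.na(j), "item '%s' not found in the response matrix", item)
  j
}

#' Read a delimited table into a response matrix
#'
#' Reads an RFC-4180 CSV file with a header row, maps each categorical
#' column's labels onto integer codes `0..K-1` in the level order declared
#' by the schema, and marks sentinel-coded or empty cells as unobserved.
#' Continuous and outcome columns are carried through as numeric
#' `caseData`; `ignore` columns are dropped.  Row order is preserved.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema A [DatasetSchema-class] declaring every column of
#'   interest.
#' @return A [ResponseMatrix-class].
#' @section Errors:
#' A label not among the declared levels raises an error naming the
#' column, row and offending label; a declared (non-ignore) column absent
#' from the file raises an error.
#' @export
readResponseTable <- function(path, schema) {
  stopIfNot(is(schema, "DatasetSchema"), "'schema' must be a DatasetSchema")
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        na.strings = character())
  specs <- schema@variables
  roles <- specRoles(specs)
  keep <- roles != "ignore"
  nm <- specNames(specs)[keep]
  missingCols <- setdiff(nm, colnames(df))
  stopIfNot(length(missingCols) == 0L, "column(s) missing from '%s': %s",
            path, paste(missingCols, collapse = ", "))
  itemSpecs <- specs[roles %in% CATEGORICAL_ROLES]
  n <- nrow(df)
  values <- matrix(NA_integer_, n, length(itemSpecs),
                   dimnames = list(NULL, specNames(itemSpecs)))
  observed <- matrix(FALSE, n, length(itemSpecs))
  for (j in seq_along(itemSpecs)) {
    sp <- itemSpecs[[j]]
    raw <- df[[sp@name]]
    miss <- raw %in% c(sp@missingSentinel, "")
    code <- match(raw, sp@levels) - 1L
    bad <- which(!miss & is.na(code))
    if (length(bad))
      stop(sprintf("column '%s', row %d: label '%s' is not a declared level",
                   sp@name, bad[1L], raw[bad[1L]]), call. = FALSE)
    values[, j] <- code
    observed[, j] <- !miss
  }
  extraSpecs <- specs[roles %in% c("continuous", "outcome")]
  caseData <- data.frame()[seq_len(n), , drop = FALSE]
  for (sp in extraSpecs) {
    raw <- df[[sp@name]]
    raw[raw %in% c(sp@missingSentinel, "")] <- NA_character_
    caseData[[sp@name]] <- suppressWarnings(as.numeric(raw))
  }
  responseMatrix(values, observed, itemSpecs, caseData)
}

#' Write a response matrix back to a delimited table
#'
#' Serializes item columns as their level labels, unobserved cells as each
#' item's missing sentinel, and appends the `caseData` columns.
#' Re-reading the file with the matching schema reproduces codes and
#' observation mask exactly.
#'
#' @param x A [ResponseMatrix-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeResponseTable <- function(x, path) {
  stopIfNot(is(x, "ResponseMatrix"), "'x' must be a ResponseMatrix")
  n <- nCases(x)
  out <- data.frame()[seq_len(n), , drop = FALSE]
  for (j in seq_len(nItems(x))) {
    sp <- x@itemSpecs[[j]]
    col <- rep(sp@missingSentinel, n)
    obs <- x@observed[, j]
    col[obs] <- sp@levels[x@values[obs, j] + 1L]
    out[[sp@name]] <- col
  }
  for (nm in colnames(x@caseData)) out[[nm]] <- x@caseData[[nm]]
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Validate a response matrix
#'
#' Screens for conditions that break or degrade estimation and reports
#' them as findings rather than errors: items whose declared categories
#' never occur among observed cells, all-missing cases, all-missing items,
#' and constant items (a single observed category).
#'
#' @param x A [ResponseMatrix-class].
#' @return A data frame with columns `type`, `item`, `case`, `message`;
#'   zero rows when the matrix is clean.
#' @export
validateResponses <- function(x) {
  stopIfNot(is(x, "ResponseMatrix"), "'x' must be a ResponseMatrix")
  findings <- list()
  add <- function(type, item = NA_character_, case = NA_integer_, message)
    findings[[length(findings) + 1L]] <<- data.frame(
      type = type, item = item, case = case, message = message)
  for (j in seq_len(nItems(x))) {
    sp <- x@itemSpecs[[j]]
    v <- x@values[x@observed[, j], j]
    if (length(v) == 0L) {
      add("all_missing_item", item = sp@name,
          message = sprintf("item '%s' has no observed responses", sp@name))
      next
    }
    seen <- sort(unique(v))
    unseen <- setdiff(seq_along(sp@levels) - 1L, seen)
    if (length(unseen))
      add("unobserved_category", item = sp@name,
          message = sprintf("item '%s': declared level(s) never observed: %s",
                            sp@name,
                            paste(sp@levels[unseen + 1L], collapse = ", ")))
    if (length(seen) == 1L)
      add("constant_item", item = sp@name,
          message = sprintf("item '%s' has a single observed category", sp@name))
  }
  allMissing <- which(rowSums(x@observed) == 0L)
  for (i in allMissing)
    add("all_missing_case", case = i,
        message = sprintf("case %d has no observed responses", i))
  if (length(findings)) do.call(rbind, findings)
  else data.frame(type = character(), item = character(),
                  case = integer(), message = character())
}
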