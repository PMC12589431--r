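#' @include AllClasses.R
NULL

#' Construct a variable specification
#'
#' @param name Column name.
#' @param role Variable role: `"binary"`, `"ordinal"`, `"nominal"`,
#'   `"continuous"`, `"outcome"` or `"ignore"`.
#' @param levels Category labels in coding order (first level = code 0).
#'   Required for categorical roles, forbidden otherwise.
#' @param missingSentinel Token treated as missing in tabular files
#'   (default `"-1"`; empty cells are always treated as missing too).
#' @return A [VariableSpec-class] object.
#' @examples
#' variableSpec("color", "ordinal", levels = c("J", "I", "H", "G", "F"))
#' @export
variableSpec <- function(name, role, levels = character(),
                         missingSentinel = "-1") {
  new("VariableSpec", name = as.character(name), role = as.character(role),
      levels = as.character(levels),
      missingSentinel = as.character(missingSentinel))
}

#' Construct a dataset schema
#'
#' @param variables List of [VariableSpec-class] objects (one per column
#'   of interest in the data file).
#' @param target Name of the categorical variable to impute.
#' @param conditional Optional name of the variable used to induce MAR
#'   missingness.
#' @return A [DatasetSchema-class] object.
#' @export
datasetSchema <- function(variables, target, conditional = NA_character_) {
  if (is(variables, "VariableSpec")) variables <- list(variables)
  new("DatasetSchema", variables = variables, target = as.character(target),
      conditional = as.character(conditional))
}

#' @describeIn variableSpec Number of declared category levels.
#' @param x A [VariableSpec-class].
#' @export
setMethod("nCategories", "VariableSpec", function(x) length(x@levels))

setMethod("show", "VariableSpec", function(object) {
  lv <- if (length(object@levels))
    paste0(" [", paste(object@levels, collapse = ", "), "]") else ""
  cat(sprintf("VariableSpec '%s' (%s)%s\n", object@name, object@role, lv))
})

setMethod("show", "DatasetSchema", function(object) {
  cat(sprintf("DatasetSchema: %d variables; target '%s'%s\n",
              length(object@variables), object@target,
              if (is.na(object@conditional)) ""
              else sprintf(", conditional '%s'", object@conditional)))
  for (v in object@variables) show(v)
})

#' Read or write a schema configuration file
#'
#' Schemas are stored as YAML with a `variables` list (fields `name`,
#' `role`, `levels`, `sentinel`), plus top-level `target` and optional
#' `conditional`.
#'
#' @param path File path.
#' @return `readSchema` returns a [DatasetSchema-class];
#'   `writeSchema` returns `path` invisibly.
#' @export
readSchema <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopIfNot(!is.null(cfg$variables), "schema file lacks a 'variables' list")
  vars <- lapply(cfg$variables, function(v) {
    variableSpec(v$name, v$role,
                 levels = if (is.null(v$levels)) character()
                          else as.character(v$levels),
                 missingSentinel = if (is.null(v$sentinel)) "-1"
                                   else as.character(v$sentinel))
  })
  datasetSchema(vars, target = cfg$target,
                conditional = if (is.null(cfg$conditional)) NA_character_
                              else cfg$conditional)
}

#' @rdname readSchema
#' @param schema A [DatasetSchema-class] to serialize.
#' @export
writeSchema <- function(schema, path) {
  stopIfNot(is(schema, "DatasetSchema"), "'schema' must be a DatasetSchema")
  vars <- lapply(schema@variables, function(v) {
    out <- list(name = v@name, role = v@role)
    if (length(v@levels)) out$levels <- as.list(v@levels)
    out$sentinel <- v@missingSentinel
    out
  })
  cfg <- list(variables = vars, target = schema@target)
  if (!is.na(schema@conditional)) cfg$conditional <- schema@conditional
  yaml::write_yaml(cfg, path)
  invisible(path)
}
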