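#' @include AllClasses.R
NULL

# Evaluate expr under a fixed seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

specNames <- function(specs)
  vapply(specs, function(v) v@name, character(1L))

specRoles <- function(specs)
  vapply(specs, function(v) v@role, character(1L))

# Clamp a proportion away from 0/1 for logit-based initialization.
clampProp <- function(p, n) pmin(pmax(p, 1 / (2 * n)), 1 - 1 / (2 * n))

stopIfNot <- function(cond, ...) if (!cond) stop(sprintf(...), call. = FALSE)
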