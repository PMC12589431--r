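#' @include missingness.R
NULL

#' Simulate latent-trait scores
#'
#' Independent standard-normal draws -- the distribution the marginal
#' maximum likelihood prior assumes for the latent trait.
#'
#' @param n Number of cases.
#' @param seed Integer seed for reproducibility.
#' @return Numeric vector of length `n`.
#' @export
simulateTheta <- function(n, seed = NULL) {
  stopIfNot(length(n) == 1L && n >= 1L, "'n' must be a positive count")
  withSeed(seed, stats::rnorm(n))
}

#' Simulate a fully observed response matrix from an item bank
#'
#' Each cell is drawn categorically from the item's model-implied
#' probability vector at the case's latent score, so empirical category
#' frequencies converge to the response-model probabilities.
#'
#' @param thetas Latent scores (one per case), e.g. from
#'   [simulateTheta()].
#' @param bank An [ItemBank-class].
#' @param seed Integer seed.
#' @return A fully observed [ResponseMatrix-class].
#' @export
simulateResponses <- function(thetas, bank, seed = NULL) {
  stopIfNot(is(bank, "ItemBank"), "'bank' must be an ItemBank")
  stopIfNot(all(is.finite(thetas)), "'thetas' must be finite")
  n <- length(thetas)
  withSeed(seed, {
    values <- matrix(NA_integer_, n, length(bank@items))
    for (j in seq_along(bank@items)) {
      P <- categoryProbs(bank@items[[j]], thetas)
      cum <- P
      for (k in seq_len(ncol(P))[-1L]) cum[, k] <- cum[, k - 1L] + P[, k]
      u <- stats::runif(n)
      values[, j] <- pmin(rowSums(u > cum), ncol(P) - 1L)
    }
    responseMatrix(values, matrix(TRUE, n, ncol(values)), bank@specs)
  })
}

#' Construct a benchmark simulation configuration
#'
#' @param n Number of cases.
#' @param bank Generating [ItemBank-class].
#' @param target Item to ampute and impute.
#' @param conditional Item whose values drive MAR amputation.
#' @param fractions Missing fractions (default the 5/10/30/50% grid).
#' @param mechanisms `"MCAR"` and/or `"MAR"`.
#' @param seed Master seed.
#' @return A [SimulationConfig-class].
#' @export
simulationConfig <- function(n, bank, target, conditional = NA_character_,
                             fractions = c(0.05, 0.10, 0.30, 0.50),
                             mechanisms = c("MCAR", "MAR"), seed = 1L) {
  new("SimulationConfig", n = as.integer(n), bank = bank,
      target = as.character(target), conditional = as.character(conditional),
      fractions = as.numeric(fractions), mechanisms = as.character(mechanisms),
      seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object)
  cat(sprintf(paste0("SimulationConfig: n = %d, %d items, target '%s',",
                     " %d mechanism(s) x %d fraction(s), seed %d\n"),
              object@n, length(object@bank@items), object@target,
              length(object@mechanisms), length(object@fractions),
              object@seed)))

#' Generate a complete dataset plus its grid of amputed variants
#'
#' Simulates one ground-truth response matrix from the configured item
#' bank and derives one amputed copy (plus mask) per mechanism-fraction
#' combination -- with the default grid, eight variants of one dataset.
#' MCAR variants get distinct seeds derived from the master seed; MAR
#' variants are deterministic given the conditional item.
#'
#' @param config A [SimulationConfig-class].
#' @return A list: `truth` (complete [ResponseMatrix-class]), `variants`
#'   (named list, each with `data` and `mask`), `manifest` (data frame of
#'   mechanism, fraction, seed and realized missing count per variant),
#'   `config`.
#' @export
makeBenchmark <- function(config) {
  stopIfNot(is(config, "SimulationConfig"), "'config' must be a SimulationConfig")
  thetas <- simulateTheta(config@n, seed = config@seed)
  truth <- simulateResponses(thetas, config@bank,
                             seed = config@seed + 1L)
  variants <- list()
  manifest <- list()
  idx <- 0L
  for (mech in config@mechanisms) {
    for (fr in config@fractions) {
      idx <- idx + 1L
      key <- sprintf("%s_%02d", tolower(mech), round(100 * fr))
      if (mech == "MCAR") {
        vseed <- config@seed + 100L + idx
        v <- induceMCAR(truth, config@target, fr, seed = vseed)
      } else {
        stopIfNot(!is.na(config@conditional),
                  "MAR variants need a conditional item in the config")
        vseed <- NA_integer_
        v <- induceMAR(truth, config@target, config@conditional, fr)
      }
      variants[[key]] <- v
      manifest[[key]] <- data.frame(
        variant = key, mechanism = mech, fraction = fr, seed = vseed,
        nMissing = length(v$mask@cases))
    }
  }
  list(truth = truth, variants = variants,
       manifest = do.call(rbind, c(manifest, make.row.names = FALSE)),
       config = config)
}

#' Write a benchmark to a directory of plain-text artifacts
#'
#' Emits the truth and every amputed variant as CSV, each variant's mask
#' as a (case, column) CSV, the schema as YAML, the generating bank as
#' YAML, and a manifest CSV listing all artifacts and seeds.
#'
#' @param benchmark Result of [makeBenchmark()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeBenchmark <- function(benchmark, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeResponseTable(benchmark$truth, file.path(dir, "truth.csv"))
  cfg <- benchmark$config
  writeSchema(datasetSchema(benchmark$truth@itemSpecs, cfg@target,
                            cfg@conditional),
              file.path(dir, "schema.yml"))
  writeItemBank(cfg@bank, file.path(dir, "bank.yml"))
  for (key in names(benchmark$variants)) {
    v <- benchmark$variants[[key]]
    writeResponseTable(v$data, file.path(dir, paste0(key, ".csv")))
    utils::write.csv(data.frame(case = v$mask@cases, column = v$mask@target),
                     file.path(dir, paste0(key, "_mask.csv")),
                     row.names = FALSE)
  }
  utils::write.csv(benchmark$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}
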