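#' @include missingness.R
NULL

# Missingness patterns of a data matrix: integer id per row plus the
# observed-column index set of each pattern.
missingPatterns <- function(Y) {
  obs <- !is.na(Y)
  id <- apply(obs, 1L, function(r) paste(as.integer(r), collapse = ""))
  ids <- unique(id)
  list(rowPattern = match(id, ids),
       observedCols = lapply(ids, function(s)
         which(strsplit(s, "")[[1]] == "1")))
}

# Observed-data log-likelihood under N(mu, Sigma) with missing cells.
mvnObsLoglik <- function(Y, mu, Sigma, pat) {
  ll <- 0
  for (p in seq_along(pat$observedCols)) {
    O <- pat$observedCols[[p]]
    if (!length(O)) next
    rows <- which(pat$rowPattern == p)
    Yo <- Y[rows, O, drop = FALSE]
    So <- Sigma[O, O, drop = FALSE]
    ch <- chol(So)
    z <- backsolve(ch, t(Yo) - mu[O], transpose = TRUE)
    ll <- ll - 0.5 * length(rows) *
      (length(O) * log(2 * pi) + 2 * sum(log(diag(ch)))) -
      0.5 * sum(z^2)
  }
  ll
}

# EM estimate of the mean vector and covariance under multivariate
# normality with arbitrary missingness (ML, n divisor).
emNormal <- function(Y, tol = 1e-8, maxIter = 200L, ridge = 1e-8) {
  n <- nrow(Y); k <- ncol(Y)
  pat <- missingPatterns(Y)
  mu <- colMeans(Y, na.rm = TRUE)
  v <- apply(Y, 2L, stats::var, na.rm = TRUE)
  v[!is.finite(v) | v <= 0] <- 1
  Sigma <- diag(v, k)
  cc <- stats::complete.cases(Y)
  if (sum(cc) > k + 1L) {
    S <- stats::cov(Y[cc, , drop = FALSE]) * (sum(cc) - 1) / sum(cc)
    if (all(is.finite(S)) && min(eigen(S, symmetric = TRUE,
                                       only.values = TRUE)$values) > 1e-10)
      Sigma <- S
  }
  llPrev <- -Inf
  for (iter in seq_len(maxIter)) {
    S1 <- numeric(k)
    S2 <- matrix(0, k, k)
    for (p in seq_along(pat$observedCols)) {
      O <- pat$observedCols[[p]]
      M <- setdiff(seq_len(k), O)
      rows <- which(pat$rowPattern == p)
      Yp <- Y[rows, , drop = FALSE]
      if (length(M)) {
        if (length(O)) {
          So <- Sigma[O, O, drop = FALSE] + diag(ridge, length(O))
          B <- Sigma[M, O, drop = FALSE] %*% solve(So)
          Yp[, M] <- matrix(mu[M], length(rows), length(M), byrow = TRUE) +
            t(B %*% (t(Yp[, O, drop = FALSE]) - mu[O]))
          Cm <- Sigma[M, M, drop = FALSE] - B %*% Sigma[O, M, drop = FALSE]
        } else {
          Yp[, M] <- matrix(mu[M], length(rows), length(M), byrow = TRUE)
          Cm <- Sigma[M, M, drop = FALSE]
        }
      }
      S1 <- S1 + colSums(Yp)
      S2 <- S2 + crossprod(Yp)
      if (length(M)) S2[M, M] <- S2[M, M] + length(rows) * Cm
    }
    mu <- S1 / n
    Sigma <- S2 / n - tcrossprod(mu)
    Sigma <- (Sigma + t(Sigma)) / 2
    ll <- mvnObsLoglik(Y, mu, Sigma, pat)
    if (is.finite(ll) && abs(ll - llPrev) < tol * (abs(llPrev) + 1)) break
    llPrev <- ll
  }
  list(mu = mu, Sigma = Sigma, loglik = ll, nIter = iter, patterns = pat)
}

littleFromMatrix <- function(Y, tol, maxIter, ridge, dataName) {
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  stopIfNot(ncol(Y) >= 2L, "Little's test needs at least 2 columns")
  keep <- rowSums(!is.na(Y)) > 0L
  Y <- Y[keep, , drop = FALSE]
  pat <- missingPatterns(Y)
  nPat <- length(pat$observedCols)
  k <- ncol(Y)
  if (nPat < 2L) {
    out <- structure(list(
      statistic = c("chi-squared" = 0), parameter = c(df = 0),
      p.value = 1, method = "Little's MCAR test",
      data.name = dataName, patterns = nPat, degenerate = TRUE),
      class = c("littleTest", "htest"))
    return(out)
  }
  est <- emNormal(Y, tol = tol, maxIter = maxIter, ridge = ridge)
  d2 <- 0; dfSum <- 0L
  for (p in seq_len(nPat)) {
    O <- est$patterns$observedCols[[p]]
    rows <- which(est$patterns$rowPattern == p)
    nj <- length(rows)
    ybar <- colMeans(Y[rows, O, drop = FALSE])
    diff <- ybar - est$mu[O]
    So <- est$Sigma[O, O, drop = FALSE] + diag(ridge, length(O))
    sol <- tryCatch(solve(So, diff), error = function(e)
      stop("singular pattern covariance in Little's test", call. = FALSE))
    d2 <- d2 + nj * sum(diff * sol)
    dfSum <- dfSum + length(O)
  }
  df <- dfSum - k
  structure(list(
    statistic = c("chi-squared" = d2), parameter = c(df = df),
    p.value = stats::pchisq(d2, df, lower.tail = FALSE),
    method = "Little's MCAR test", data.name = dataName,
    patterns = nPat, degenerate = FALSE, em = est[c("mu", "Sigma", "nIter")]),
    class = c("littleTest", "htest"))
}

#' @rdname littleMCARTest
#' @export
setMethod("littleMCARTest", "matrix",
  function(x, columns = NULL, tol = 1e-8, maxIter = 200L, ridge = 1e-8) {
    nm <- deparse(substitute(x))
    if (!is.null(columns)) x <- x[, columns, drop = FALSE]
    littleFromMatrix(x, tol, maxIter, ridge, nm)
  })

#' @rdname littleMCARTest
#' @export
setMethod("littleMCARTest", "data.frame",
  function(x, columns = NULL, tol = 1e-8, maxIter = 200L, ridge = 1e-8) {
    nm <- deparse(substitute(x))
    if (!is.null(columns)) x <- x[, columns, drop = FALSE]
    littleFromMatrix(as.matrix(x), tol, maxIter, ridge, nm)
  })

# Numeric encoding of a ResponseMatrix for Little's test: binary/ordinal
# items as integer codes, nominal items as K-1 level indicators (the first
# level dropped -- K indicators would sum to 1 and make every pattern
# covariance singular), numeric caseData columns as-is.
encodeForLittle <- function(x, columns = NULL) {
  nm <- itemNames(x)
  use <- if (is.null(columns)) c(nm, colnames(x@caseData)) else columns
  cols <- list()
  for (cn in use) {
    if (cn %in% nm) {
      j <- itemIndex(x, cn)
      sp <- x@itemSpecs[[j]]
      v <- x@values[, j]
      v[!x@observed[, j]] <- NA_integer_
      if (sp@role == "nominal") {
        K <- length(sp@levels)
        for (k in 2:K)
          cols[[paste0(cn, ".", sp@levels[k])]] <- as.numeric(v == k - 1L)
      } else {
        cols[[cn]] <- as.numeric(v)
      }
    } else if (cn %in% colnames(x@caseData)) {
      cols[[cn]] <- as.numeric(x@caseData[[cn]])
    } else stop(sprintf("column '%s' not found", cn), call. = FALSE)
  }
  do.call(cbind, cols)
}

#' @rdname littleMCARTest
#' @export
setMethod("littleMCARTest", "ResponseMatrix",
  function(x, columns = NULL, tol = 1e-8, maxIter = 200L, ridge = 1e-8) {
    nm <- deparse(substitute(x))
    littleFromMatrix(encodeForLittle(x, columns), tol, maxIter, ridge, nm)
  })
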