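# Fixture builders and independent oracles used across the suite.
# Oracles implement the response functions and marginal likelihood with
# plain arithmetic (exp/loops), separate from the package's code paths.

twoPLBankFixture <- function(J = 10, seed = 1, aRange = c(0.8, 2),
                             bRange = c(-2, 2)) {
  set.seed(seed)
  itemBank(lapply(seq_len(J), function(j)
    twoPLItem(runif(1, aRange[1], aRange[2]), runif(1, bRange[1], bRange[2]),
              name = paste0("u", j))))
}

grmBankFixture <- function(J = 10, seed = 2, K = 5) {
  set.seed(seed)
  itemBank(lapply(seq_len(J), function(j) {
    th <- sort(runif(K - 1, -2, 2)) + cumsum(c(0, rep(0.15, K - 2)))
    grmItem(runif(1, 0.8, 2), th, name = paste0("g", j))
  }))
}

nrmBankFixture <- function(J = 10, seed = 3, K = 4) {
  set.seed(seed)
  itemBank(lapply(seq_len(J), function(j)
    nrmItem(c(0, sort(runif(K - 1, -1, 2))), c(0, runif(K - 1, -1, 1)),
            name = paste0("n", j))))
}

# correlated multivariate-normal fixture for Little's-test studies
mvnFixture <- function(n, k = 4, rho = 0.5, seed = 1) {
  set.seed(seed)
  L <- chol(rho + diag(1 - rho, k))
  Y <- matrix(rnorm(n * k), n, k) %*% L
  colnames(Y) <- paste0("v", seq_len(k))
  Y
}

## ---- independent oracles --------------------------------------------------

oracle2PL <- function(theta, a, b) {
  e <- exp(a * (theta - b))
  e / (1 + e)
}

oracleGRMProbs <- function(theta, a, thresholds) {
  bstar <- c(1, vapply(thresholds, function(b) oracle2PL(theta, a, b),
                       numeric(1)), 0)
  bstar[-length(bstar)] - bstar[-1]
}

oracleNRMProbs <- function(theta, slopes, intercepts) {
  e <- exp(slopes * theta + intercepts)
  e / sum(e)
}

oracleItemProb <- function(item, theta, code) {
  if (is(item, "TwoPLItem")) {
    p1 <- oracle2PL(theta, item@a, item@b)
    if (code == 1) p1 else 1 - p1
  } else if (is(item, "GRMItem")) {
    oracleGRMProbs(theta, item@a, item@thresholds)[code + 1]
  } else {
    oracleNRMProbs(theta, item@slopes, item@intercepts)[code + 1]
  }
}

# Marginal log-likelihood by direct summation: for every case, a plain
# double loop over nodes and observed items.
oracleMarginalLoglik <- function(rm, items, nodes, weights) {
  v <- responseValues(rm)
  obs <- observedMask(rm)
  ll <- 0
  for (i in seq_len(nrow(v))) {
    Li <- 0
    for (q in seq_along(nodes)) {
      f <- 1
      for (j in which(obs[i, ]))
        f <- f * oracleItemProb(items[[j]], nodes[q], v[i, j])
      Li <- Li + weights[q] * f
    }
    ll <- ll + log(Li)
  }
  ll
}

# EAP by fine-grid integration on a wider interval, all plain arithmetic.
oracleEAP <- function(codes, items, nGrid = 10001, bound = 6) {
  nodes <- seq(-bound, bound, length.out = nGrid)
  w <- dnorm(nodes); w <- w / sum(w)
  L <- rep(1, nGrid)
  for (j in which(!is.na(codes)))
    L <- L * vapply(nodes, function(t) oracleItemProb(items[[j]], t, codes[j]),
                    numeric(1))
  post <- w * L
  sum(nodes * post) / sum(post)
}

# small mixed-type schema + CSV on disk; returns list(path, schema)
writeMixedFixtureCSV <- function(dir = tempdir()) {
  path <- file.path(dir, paste0("fix-", as.integer(stats::runif(1, 1, 1e8)), ".csv"))
  df <- data.frame(
    color = c("J", "I", "-1", "H", "", "G", "F", "J", "I", "H"),
    hibp = c("no", "yes", "yes", "-1", "no", "no", "yes", "no", "-1", "yes"),
    age = c(61, 45, 50, 39, 71, 55, 48, 66, 59, 44),
    outcome = rnorm(10),
    junk = letters[1:10])
  write.csv(df, path, row.names = FALSE)
  schema <- datasetSchema(list(
    variableSpec("color", "ordinal", levels = c("J", "I", "H", "G", "F")),
    variableSpec("hibp", "binary", levels = c("no", "yes")),
    variableSpec("age", "continuous"),
    variableSpec("outcome", "outcome"),
    variableSpec("junk", "ignore")),
    target = "hibp", conditional = "age")
  list(path = path, schema = schema)
}
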