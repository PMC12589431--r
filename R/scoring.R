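#' @include fit-em.R
NULL

# Posterior over quadrature nodes for every case: rows of prior-weighted
# likelihood, normalized.  Rows with no observed items reduce to the prior.
posteriorMatrix <- function(values, observed, items, quad) {
  n <- nrow(values)
  L <- likelihoodMatrix(values, observed, items, quad@nodes)
  post <- L * rep(quad@weights, each = n)
  tot <- rowSums(post)
  if (any(!is.finite(tot)) || any(tot <= 0))
    stop("zero posterior mass for at least one case", call. = FALSE)
  post / tot
}

eapFromPosterior <- function(post, nodes, nObserved) {
  eap <- drop(post %*% nodes)
  m2 <- drop(post %*% nodes^2)
  data.frame(eap = eap, psd = sqrt(pmax(m2 - eap^2, 0)),
             nObserved = nObserved)
}

#' @rdname eapTheta
#' @export
setMethod("eapTheta", "ResponseMatrix", function(object, fit) {
  stopIfNot(is(fit, "IRTFit"), "'fit' must be an IRTFit")
  stopIfNot(nItems(object) == length(fit@items),
            "matrix and fit disagree on the number of items")
  post <- posteriorMatrix(object@values, object@observed, fit@items,
                          fit@quadrature)
  eapFromPosterior(post, fit@quadrature@nodes, rowSums(object@observed))
})

#' @rdname eapTheta
#' @export
setMethod("eapTheta", "numeric", function(object, fit) {
  stopIfNot(is(fit, "IRTFit"), "'fit' must be an IRTFit")
  v <- matrix(as.integer(object), nrow = 1L)
  post <- posteriorMatrix(v, !is.na(v), fit@items, fit@quadrature)
  eapFromPosterior(post, fit@quadrature@nodes, sum(!is.na(v)))
})
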