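#' @include AllClasses.R
NULL

#' Build a fixed quadrature grid for the latent trait
#'
#' Equally spaced nodes on `[-bound, bound]` with standard-normal density
#' weights renormalized to sum to 1 -- the fixed-grid integration used by
#' Bock-Aitkin marginal maximum likelihood and EAP scoring under the
#' standard-normal latent-trait prior.
#'
#' @param nNodes Number of nodes (at least 3; default 41).
#' @param bound Half-width of the grid (default 5).
#' @return A [Quadrature-class].
#' @examples
#' q <- buildQuadrature(41, 5)
#' sum(quadWeights(q))            # 1
#' sum(quadWeights(q) * quadNodes(q))  # 0 by symmetry
#' @export
buildQuadrature <- function(nNodes = 41L, bound = 5) {
  stopIfNot(length(nNodes) == 1L && nNodes >= 3L,
            "nNodes must be a single integer >= 3")
  stopIfNot(length(bound) == 1L && bound > 0, "bound must be positive")
  nodes <- seq(-bound, bound, length.out = as.integer(nNodes))
  w <- stats::dnorm(nodes)
  new("Quadrature", nodes = nodes, weights = w / sum(w))
}

#' @describeIn buildQuadrature Node positions.
#' @param q A [Quadrature-class].
#' @export
quadNodes <- function(q) q@nodes

#' @describeIn buildQuadrature Normalized prior weights.
#' @export
quadWeights <- function(q) q@weights

setMethod("show", "Quadrature", function(object)
  cat(sprintf("Quadrature: %d nodes on [%.3g, %.3g]\n",
              length(object@nodes), min(object@nodes), max(object@nodes))))
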