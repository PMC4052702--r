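#' @import methods
#' @importFrom stats phyper sd rnorm runif t.test p.adjust cor
#' @importFrom utils read.delim write.table
NULL

#' PLSModel: a fitted single-response NIPALS partial least squares model
#'
#' Holds the weights, scores, loadings and per-component explained response
#' sum of squares of a PLS1 fit on an autoscaled expression matrix, together
#' with the preprocessing record (per-probe centers and scales, response
#' coding) needed to make the fit reproducible.
#'
#' @slot weights p x A matrix W of probe weights; each column has unit
#'   Euclidean norm.
#' @slot scores n x A matrix T of sample scores (latent variables); columns
#'   are mutually orthogonal.
#' @slot xLoadings p x A matrix P of predictor loadings.
#' @slot yLoadings length-A numeric q of response loadings.
#' @slot ssy length-A numeric, explained response sum of squares per
#'   component, \eqn{SSY_a = q_a^2 t_a^T t_a}.
#' @slot ssyTotal total centered-response sum of squares before extraction.
#' @slot probeIds probe identifiers for the rows of `weights` (probes
#'   retained after zero-variance filtering).
#' @slot sampleIds sample identifiers for the rows of `scores`.
#' @slot preprocessing list recording the autoscaling: `center`, `scale`
#'   (per retained probe), `droppedProbes` (zero-variance probes excluded),
#'   `yMean` (mean of the 0/1 class coding) and `scaled` (logical).
#' @slot tol numeric tolerance governing early stop of component extraction.
#'
#' @seealso [nipalsPls()], [vip()], [sampleScores()]
#' @export
setClass("PLSModel",
  representation(
    weights = "matrix",
    scores = "matrix",
    xLoadings = "matrix",
    yLoadings = "numeric",
    ssy = "numeric",
    ssyTotal = "numeric",
    probeIds = "character",
    sampleIds = "character",
    preprocessing = "list",
    tol = "numeric"
  )
)

setValidity("PLSModel", function(object) {
  msg <- character(0)
  A <- ncol(object@weights)
  if (ncol(object@scores) != A || ncol(object@xLoadings) != A ||
      length(object@yLoadings) != A || length(object@ssy) != A)
    msg <- c(msg, "weights, scores, xLoadings, yLoadings and ssy must agree on the number of components")
  if (nrow(object@weights) != length(object@probeIds))
    msg <- c(msg, "weights rows must match probeIds")
  if (nrow(object@scores) != length(object@sampleIds))
    msg <- c(msg, "scores rows must match sampleIds")
  if (A >= 1) {
    wn <- sqrt(colSums(object@weights^2))
    if (any(abs(wn - 1) > 1e-10))
      msg <- c(msg, "each weight column must have unit Euclidean norm (tol 1e-10)")
    if (A >= 2) {
      G <- crossprod(object@scores)
      nrm <- sqrt(diag(G))
      off <- abs(G) / outer(nrm, nrm)
      diag(off) <- 0
      if (any(off > 1e-8))
        msg <- c(msg, "score columns must be mutually orthogonal (rel. tol 1e-8)")
    }
    if (any(object@ssy < 0))
      msg <- c(msg, "per-component explained y sums of squares must be nonnegative")
    if (sum(object@ssy) > object@ssyTotal * (1 + 1e-8))
      msg <- c(msg, "sum of explained y sums of squares cannot exceed the total y sum of squares")
  }
  if (length(msg)) msg else TRUE
})

#' PermutationNull: empirical VIP null distribution under label permutation
#'
#' Stores the VIP vectors recomputed under random shuffles of the class
#' labels (response permutation with the expression matrix fixed), the seed
#' that makes them reproducible, and the count of degenerate permutations
#' whose fit explained no response variance (their VIP rows are all zero,
#' a conservative convention).
#'
#' @slot nullVip n_permutations x p matrix of VIP values under the null.
#' @slot seed integer seed used for the permutation stream.
#' @slot nDegenerate number of permutations recorded as all-zero rows.
#'
#' @seealso [permutationNull()], [empiricalFdr()]
#' @export
setClass("PermutationNull",
  representation(
    nullVip = "matrix",
    seed = "integer",
    nDegenerate = "integer"
  )
)

setValidity("PermutationNull", function(object) {
  msg <- character(0)
  if (nrow(object@nullVip) < 1)
    msg <- c(msg, "at least one permutation is required")
  if (any(object@nullVip < 0))
    msg <- c(msg, "VIP values must be nonnegative")
  p <- ncol(object@nullVip)
  rs <- rowSums(object@nullVip^2)
  nonzero <- rs > 0
  if (any(abs(rs[nonzero] - p) > 1e-6 * p))
    msg <- c(msg, "each non-degenerate null VIP row must satisfy sum(vip^2) = p (rel. tol 1e-6)")
  if (length(msg)) msg else TRUE
})

#' InteractionNetwork: interaction graph induced by selected genes
#'
#' An undirected simple graph over the selected (differentially expressed)
#' genes: an input edge is kept only when both endpoints are selected;
#' isolated selected genes remain as degree-0 nodes. Each node carries its
#' expression direction (up/down in patients) and the hub threshold is the
#' exclusive degree cutoff (degree strictly greater is a hub).
#'
#' @slot graph an [igraph::igraph] undirected simple graph.
#' @slot direction named character, "up" or "down" per node.
#' @slot hubThreshold exclusive integer degree threshold for hub calls.
#'
#' @seealso [buildNetwork()], [nodeDegrees()], [hubGenes()], [exportNetwork()]
#' @export
setClass("InteractionNetwork",
  representation(
    graph = "ANY",
    direction = "character",
    hubThreshold = "integer"
  )
)

setValidity("InteractionNetwork", function(object) {
  msg <- character(0)
  g <- object@graph
  if (!igraph::is_igraph(g)) {
    msg <- c(msg, "graph slot must be an igraph object")
    return(msg)
  }
  if (igraph::is_directed(g))
    msg <- c(msg, "graph must be undirected")
  if (igraph::any_multiple(g) || any(igraph::which_loop(g)))
    msg <- c(msg, "graph must be simple (no multi-edges or self-loops)")
  nodes <- igraph::V(g)$name
  if (!setequal(names(object@direction), nodes))
    msg <- c(msg, "direction must be named by exactly the graph's nodes")
  if (!all(object@direction %in% c("up", "down")))
    msg <- c(msg, "direction values must be 'up' or 'down'")
  if (length(object@hubThreshold) != 1L || object@hubThreshold < 0L)
    msg <- c(msg, "hubThreshold must be a single nonnegative integer")
  if (length(msg)) msg else TRUE
})
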