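#' Number of latent components in a PLS model
#' @param object a [PLSModel-class]
#' @return integer component count
#' @export
setGeneric("nComponents", function(object) standardGeneric("nComponents"))

#' Probe weight matrix of a PLS model
#' @param object a [PLSModel-class]
#' @return p x A matrix of unit-norm weight columns
#' @export
setGeneric("plsWeights", function(object) standardGeneric("plsWeights"))

#' Sample score matrix (latent variables) of a PLS model
#' @param object a [PLSModel-class]
#' @return n x A matrix of sample scores
#' @export
setGeneric("plsScores", function(object) standardGeneric("plsScores"))

#' Predictor loading matrix of a PLS model
#' @param object a [PLSModel-class]
#' @return p x A loading matrix
#' @export
setGeneric("plsLoadings", function(object) standardGeneric("plsLoadings"))

#' Per-component explained response sum of squares
#' @param object a [PLSModel-class]
#' @return length-A numeric vector
#' @export
setGeneric("explainedSSY", function(object) standardGeneric("explainedSSY"))

#' Variable importance on the projection (VIP)
#'
#' @param object a fitted [PLSModel-class]
#' @return named nonnegative numeric vector of per-probe VIP scores
#'   satisfying \eqn{\sum_j VIP_j^2 = p}
#' @export
setGeneric("vip", function(object) standardGeneric("vip"))

#' Fitted response values of a PLS model
#' @param object a [PLSModel-class]
#' @return numeric vector \eqn{\hat y = \sum_a q_a t_a} on the centered scale
#' @export
setGeneric("fittedY", function(object) standardGeneric("fittedY"))

#' Per-node degrees of an interaction network
#' @param object an [InteractionNetwork-class]
#' @return named integer vector of distinct-neighbor counts
#' @export
setGeneric("nodeDegrees", function(object) standardGeneric("nodeDegrees"))

#' Hub genes of an interaction network
#'
#' Nodes whose degree strictly exceeds the threshold ("more than" reading,
#' exclusive).
#'
#' @param object an [InteractionNetwork-class]
#' @param minExclusive exclusive degree threshold; defaults to the
#'   network's stored threshold (10)
#' @return character vector of hub gene identifiers, sorted by decreasing degree
#' @export
setGeneric("hubGenes", function(object, minExclusive = NULL) standardGeneric("hubGenes"))
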