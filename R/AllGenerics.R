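#' @import methods
#' @importFrom stats cor cor.test t.test wilcox.test loess predict quantile
#'   rpois sd setNames complete.cases ecdf median mad rnorm runif
#' @importFrom utils head tail
NULL

#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))

#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @export
setGeneric("nBins", function(x, chrom = NULL) standardGeneric("nBins"))

#' @export
setGeneric("genomeGrid", function(x) standardGeneric("genomeGrid"))

#' @export
setGeneric("trackValues", function(x, chrom = NULL) standardGeneric("trackValues"))

#' @export
setGeneric("valueKind", function(x) standardGeneric("valueKind"))

#' @export
setGeneric("totalContacts", function(x) standardGeneric("totalContacts"))

#' @export
setGeneric("cisMatrix", function(x, chrom) standardGeneric("cisMatrix"))

#' @export
setGeneric("binWeights", function(x, chrom = NULL) standardGeneric("binWeights"))

#' @export
setGeneric("anchorOne", function(x) standardGeneric("anchorOne"))

#' @export
setGeneric("anchorTwo", function(x) standardGeneric("anchorTwo"))

#' @export
setGeneric("loopLengths", function(x) standardGeneric("loopLengths"))

#' @export
setGeneric("aggregateMatrix", function(x) standardGeneric("aggregateMatrix"))

#' @export
setGeneric("backgroundMatrix", function(x) standardGeneric("backgroundMatrix"))

#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))

#' @export
setGeneric("perFeatureValues", function(x) standardGeneric("perFeatureValues"))

#' @export
setGeneric("aggregateStats", function(x) standardGeneric("aggregateStats"))
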