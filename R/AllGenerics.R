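#' @title Accessor generics
#' @name nmrmix-accessors
#' @description Accessors for the core classes; slots are never reached
#'   into directly by user code.
NULL

#' @export
setGeneric("ppmAxis", function(x) standardGeneric("ppmAxis"))
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @export
setGeneric("spectrumName", function(x) standardGeneric("spectrumName"))
#' @export
setGeneric("spectrumMeta", function(x) standardGeneric("spectrumMeta"))
#' @export
setGeneric("pairLabels", function(x) standardGeneric("pairLabels"))
#' @export
setGeneric("pairTargets", function(x) standardGeneric("pairTargets"))
#' @export
setGeneric("pairComposition", function(x) standardGeneric("pairComposition"))
#' @export
setGeneric("pairPartition", function(x) standardGeneric("pairPartition"))
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))
#' @export
setGeneric("modelWeights", function(x) standardGeneric("modelWeights"))
#' @export
setGeneric("screenTable", function(x) standardGeneric("screenTable"))
#' @export
setGeneric("candidates", function(x) standardGeneric("candidates"))
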