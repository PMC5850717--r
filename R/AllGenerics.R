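# Generics for the estimator and accessor surface.

#' @export
setGeneric("thetaWatterson", function(x, ...) standardGeneric("thetaWatterson"))

#' @export
setGeneric("thetaBeta", function(x, p = 2, ...) standardGeneric("thetaBeta"))

#' @export
setGeneric("betaScore", function(x, p = 2, ...) standardGeneric("betaScore"))

#' @export
setGeneric("tajimasD", function(x, ...) standardGeneric("tajimasD"))

#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @export
setGeneric("derivedCounts", function(x) standardGeneric("derivedCounts"))

#' @export
setGeneric("sampleSizes", function(x) standardGeneric("sampleSizes"))

#' @export
setGeneric("contigs", function(x) standardGeneric("contigs"))

#' @export
setGeneric("isFolded", function(x) standardGeneric("isFolded"))

#' @export
setGeneric("classCounts", function(x) standardGeneric("classCounts"))

#' @export
setGeneric("coreCount", function(x) standardGeneric("coreCount"))

#' @export
setGeneric("sampleSize", function(x) standardGeneric("sampleSize"))

#' @export
setGeneric("simSites", function(x) standardGeneric("simSites"))

#' @export
setGeneric("substitutions", function(x) standardGeneric("substitutions"))

#' @export
setGeneric("foldSpectrum", function(x) standardGeneric("foldSpectrum"))
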