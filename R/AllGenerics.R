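#' @export
setGeneric("sampleNames", function(x) standardGeneric("sampleNames"))

#' @export
setGeneric("spikeCounts", function(object) standardGeneric("spikeCounts"))

#' @export
setGeneric("initialFactors", function(object) standardGeneric("initialFactors"))

#' @export
setGeneric("adjustedFactors",
           function(object) standardGeneric("adjustedFactors"))

#' @export
setGeneric("motifWidth", function(x) standardGeneric("motifWidth"))

#' @export
setGeneric("motifName", function(x) standardGeneric("motifName"))

#' @export
setGeneric("motifProbs", function(x) standardGeneric("motifProbs"))

#' @export
setGeneric("motifConsensus", function(x) standardGeneric("motifConsensus"))

#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))
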