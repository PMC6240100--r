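#' @include AllClasses.R
NULL

#' @export
setGeneric("runId", function(object) standardGeneric("runId"))

#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' @export
setGeneric("techRep", function(object) standardGeneric("techRep"))

#' @export
setGeneric("scanTimes", function(object) standardGeneric("scanTimes"))

#' @export
setGeneric("peakLists", function(object) standardGeneric("peakLists"))

#' @export
setGeneric("nScans", function(object) standardGeneric("nScans"))

#' @export
setGeneric("peptideKey", function(object) standardGeneric("peptideKey"))

#' @export
setGeneric("xicArea", function(object) standardGeneric("xicArea"))

#' @export
setGeneric("xicPoints", function(object) standardGeneric("xicPoints"))

#' @export
setGeneric("quantLevel", function(object) standardGeneric("quantLevel"))

#' @export
setGeneric("intensityMatrix", function(object) standardGeneric("intensityMatrix"))

#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' @export
setGeneric("nRuns", function(object) standardGeneric("nRuns"))

#' @export
setGeneric("truePeptides", function(object) standardGeneric("truePeptides"))

#' @export
setGeneric("trueAbundance", function(object) standardGeneric("trueAbundance"))

#' @export
setGeneric("presenceMatrix", function(object) standardGeneric("presenceMatrix"))
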