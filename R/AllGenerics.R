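#' @include AllClasses.R
NULL

#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @export
setGeneric("recordingDuration", function(x) standardGeneric("recordingDuration"))

#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))

#' @export
setGeneric("nSpikes", function(x) standardGeneric("nSpikes"))

#' @export
setGeneric("rateValues", function(x) standardGeneric("rateValues"))

#' @export
setGeneric("timeAxis", function(x) standardGeneric("timeAxis"))

#' @export
setGeneric("trialTable", function(x) standardGeneric("trialTable"))

#' @export
setGeneric("recordingMeta", function(x) standardGeneric("recordingMeta"))
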