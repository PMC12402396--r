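#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a RawRecording
#'
#' @param samples numeric voltage samples (microvolts).
#' @param fs sampling rate (Hz).
#' @param meta named list of metadata.
#' @return A [RawRecording-class] object.
#' @export
rawRecording <- function(samples, fs, meta = list()) {
  new("RawRecording", samples = as.numeric(samples), fs = as.numeric(fs),
      meta = meta)
}

#' Construct a SpikeTrain
#'
#' @param times spike times (s), strictly increasing.
#' @param fs sampling rate (Hz) of the train representation.
#' @param duration recording duration (s).
#' @param meta named list of metadata.
#' @return A [SpikeTrain-class] object.
#' @export
spikeTrain <- function(times, fs, duration, meta = list()) {
  new("SpikeTrain", times = as.numeric(times), fs = as.numeric(fs),
      duration = as.numeric(duration), meta = meta)
}

#' @describeIn samples Voltage samples of a recording (microvolts).
#' @param x object.
#' @export
setMethod("samples", "RawRecording", function(x) x@samples)

#' @describeIn samplingRate Sampling rate of a recording (Hz).
#' @param x object.
#' @export
setMethod("samplingRate", "RawRecording", function(x) x@fs)

#' @export
setMethod("samplingRate", "SpikeTrain", function(x) x@fs)

#' @export
setMethod("samplingRate", "RateSeries", function(x) x@fs)

#' @describeIn recordingDuration Duration in seconds.
#' @param x object.
#' @export
setMethod("recordingDuration", "RawRecording",
          function(x) length(x@samples) / x@fs)

#' @export
setMethod("recordingDuration", "SpikeTrain", function(x) x@duration)

#' @export
setMethod("recordingDuration", "GroundTruthSpikes", function(x) x@duration)

#' @describeIn spikeTimes Spike times in seconds.
#' @param x object.
#' @export
setMethod("spikeTimes", "SpikeTrain", function(x) x@times)

#' @export
setMethod("spikeTimes", "GroundTruthSpikes", function(x) x@times)

#' @describeIn nSpikes Number of spikes.
#' @param x object.
#' @export
setMethod("nSpikes", "SpikeTrain", function(x) length(x@times))

#' @export
setMethod("nSpikes", "GroundTruthSpikes", function(x) length(x@times))

#' @describeIn rateValues Rate values (Hz) of a rate series.
#' @param x object.
#' @export
setMethod("rateValues", "RateSeries", function(x) x@rate)

#' @describeIn timeAxis Sample times (s) of a rate series.
#' @param x object.
#' @export
setMethod("timeAxis", "RateSeries",
          function(x) (seq_along(x@rate) - 1) / x@fs)

#' @describeIn trialTable Trial table of a startle session.
#' @param x object.
#' @export
setMethod("trialTable", "StartleSession", function(x) x@trials)

#' @describeIn recordingMeta Metadata list.
#' @param x object.
#' @export
setMethod("recordingMeta", "RawRecording", function(x) x@meta)

#' @export
setMethod("recordingMeta", "SpikeTrain", function(x) x@meta)

#' @export
setMethod("recordingMeta", "RateSeries", function(x) x@meta)

#' @export
setMethod("recordingMeta", "StartleSession", function(x) x@meta)

setMethod("show", "RawRecording", function(object) {
  m <- object@meta
  cat(sprintf("RawRecording: %d samples @ %g Hz (%.2f s)\n",
              length(object@samples), object@fs,
              length(object@samples) / object@fs))
  if (length(m))
    cat("  meta:", paste(names(m), unlist(lapply(m, function(v)
      paste(format(v), collapse = ","))), sep = "=", collapse = " "), "\n")
})

setMethod("show", "SpikeTrain", function(object) {
  cat(sprintf("SpikeTrain: %d spikes over %.2f s (%.3f Hz) @ %g Hz\n",
              length(object@times), object@duration,
              length(object@times) / object@duration, object@fs))
})

setMethod("show", "RateSeries", function(object) {
  cat(sprintf(
    "RateSeries (%s): %d samples @ %g Hz, %.3g s boxcar, mean %.3f Hz\n",
    object@epoch, length(object@rate), object@fs, object@window,
    mean(object@rate)))
})

setMethod("show", "StartleSession", function(object) {
  tab <- table(object@trials$trial_type)
  cat("StartleSession:",
      paste(names(tab), as.integer(tab), sep = "=", collapse = " "), "\n")
})

setMethod("show", "EphysPreset", function(object) {
  cat(sprintf(
    "EphysPreset '%s': %.2f +/- %.2f Hz, short-ISI %.4f, %gs x %d animals\n",
    object@name, object@groupMeanRate, object@betweenAnimalSd,
    object@shortIsiFraction, object@duration, object@nAnimals))
  if (length(object@stimulation))
    cat("  stimulation:", paste(names(object@stimulation),
        unlist(object@stimulation), sep = "=", collapse = " "), "\n")
})

setMethod("show", "BehaviorPreset", function(object) {
  cat(sprintf(
    "BehaviorPreset '%s': GPIAS %.2f%%, PPI %.2f%%, baseline %g, cv %.2f\n",
    object@name, object@gpiasTrue, object@ppiTrue, object@baselineAmp,
    object@trialCv))
})

setMethod("show", "IsiMixtureParams", function(object) {
  cat(sprintf(
    "IsiMixtureParams: w=%.4f Gamma(shape %g, mean %g ms) + Exp(mean %.3f ms), refractory %g ms\n",
    object@burstWeight, object@burstShape, object@burstMean,
    object@tonicMean, object@refractory))
})

setMethod("show", "GroundTruthSpikes", function(object) {
  cat(sprintf(
    "GroundTruthSpikes: %d spikes over %.1f s (target %.2f Hz, preset '%s', seed %d)\n",
    length(object@times), object@duration, object@trueRate,
    object@presetName, object@seed))
})
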