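#' Single-channel extracellular voltage recording
#'
#' Holds one continuous voltage trace in microvolts at a fixed sampling rate,
#' together with free-form metadata (animal id, group, phase, preset, seed).
#' Raw traces from the generator and band-pass filtered traces share this
#' class; `recordingMeta(x)$filtered` records whether [bandpass()] has been
#' applied.
#'
#' @slot samples numeric voltage samples (microvolts).
#' @slot fs sampling rate in Hz.
#' @slot meta named list of metadata.
#'
#' @seealso [rawRecording()], [bandpass()], [detectSpikes()]
#' @export
setClass("RawRecording",
  representation(samples = "numeric", fs = "numeric", meta = "list"))

setValidity("RawRecording", function(object) {
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    return("'fs' must be a single positive number")
  if (anyNA(object@samples))
    return("'samples' must not contain NA")
  TRUE
})

#' Detected spike train
#'
#' Spike times (seconds, strictly increasing) detected on a recording of
#' known duration and sampling rate. The binary 0/1 representation at `fs`
#' is computed on demand by [toBinaryTrain()].
#'
#' @slot times numeric spike times in seconds, strictly increasing.
#' @slot fs sampling rate (Hz) at which the train is represented.
#' @slot duration recording duration in seconds.
#' @slot meta named list (source recording id, detection parameters, ...).
#'
#' @seealso [detectSpikes()], [toBinaryTrain()], [downsampleTrain()], [sfr()]
#' @export
setClass("SpikeTrain",
  representation(times = "numeric", fs = "numeric", duration = "numeric",
                 meta = "list"))

setValidity("SpikeTrain", function(object) {
  t <- object@times
  if (anyNA(t)) return("spike times must not contain NA")
  if (length(t) > 1L && any(diff(t) <= 0))
    return("spike times must be strictly increasing")
  if (length(t) && (t[1L] < 0 || t[length(t)] > object@duration))
    return("spike times must lie within [0, duration]")
  if (object@fs <= 0 || object@duration <= 0)
    return("'fs' and 'duration' must be positive")
  TRUE
})

#' Instantaneous firing-rate series
#'
#' Firing rate in Hz over time, from a centered boxcar applied to a binary
#' spike train (one rate value per train sample).
#'
#' @slot rate numeric rate values (Hz), one per sample.
#' @slot fs sampling rate of the series (Hz).
#' @slot window boxcar window length in seconds.
#' @slot epoch epoch label, e.g. "before" or "after".
#' @slot meta named list of metadata.
#'
#' @seealso [sfr()], [meanSfr()], [timepointScan()]
#' @export
setClass("RateSeries",
  representation(rate = "numeric", fs = "numeric", window = "numeric",
                 epoch = "character", meta = "list"))

setValidity("RateSeries", function(object) {
  if (anyNA(object@rate) || any(object@rate < -1e-9))
    return("rate values must be non-negative and non-NA")
  if (object@fs <= 0 || object@window <= 0)
    return("'fs' and 'window' must be positive")
  TRUE
})

#' Acoustic startle session
#'
#' Typed startle trials with peak-to-peak response amplitudes. A full
#' session carries a gap-detection (GPIAS) block of gap/no-gap trials and a
#' prepulse (PPI) block of pulse/prepulse/no-stimulus trials. Per-trial
#' platform waveforms are optional; when present, [peakToPeak()] can
#' re-derive the amplitudes.
#'
#' @slot trials data.frame with columns `trial_index`, `block`,
#'   `trial_type` (gap, no_gap, pulse, prepulse, no_stim), `amplitude`.
#' @slot waveforms list of numeric waveforms (possibly empty), parallel to
#'   rows of `trials`.
#' @slot waveformFs sampling rate of the waveforms (Hz), NA when absent.
#' @slot meta named list (animal, group, phase, preset, seed).
#'
#' @seealso [genStartleSession()], [gpiasIndex()], [ppiIndex()]
#' @export
setClass("StartleSession",
  representation(trials = "data.frame", waveforms = "list",
                 waveformFs = "numeric", meta = "list"))

.startleTypes <- c("gap", "no_gap", "pulse", "prepulse", "no_stim")

setValidity("StartleSession", function(object) {
  tr <- object@trials
  need <- c("trial_index", "block", "trial_type", "amplitude")
  if (!all(need %in% names(tr)))
    return(paste("trials must have columns", paste(need, collapse = ", ")))
  if (!all(tr$trial_type %in% .startleTypes))
    return("unknown trial_type")
  if (any(tr$amplitude < 0)) return("amplitudes must be non-negative")
  if (length(object@waveforms) && length(object@waveforms) != nrow(tr))
    return("waveforms must be empty or one per trial")
  TRUE
})

#' Ephys condition preset
#'
#' One experimental condition of the synthetic-recording generator: group
#' mean spontaneous firing rate, between-animal SD, target fraction of short
#' (<5 ms) inter-spike intervals, recording duration and group size.
#' Post-stimulation presets additionally carry the stimulation descriptors
#' (pulse frequency/amplitude/width) as inert metadata.
#'
#' @slot name preset label.
#' @slot groupMeanRate group mean firing rate (Hz).
#' @slot betweenAnimalSd between-animal SD of the rate (Hz).
#' @slot shortIsiFraction target P(ISI < 5 ms), in [0, 1).
#' @slot duration recording duration (s).
#' @slot nAnimals animals per group.
#' @slot stimulation named list of stimulation descriptors (may be empty).
#'
#' @seealso [ephysPresets()], [genGroup()]
#' @export
setClass("EphysPreset",
  representation(name = "character", groupMeanRate = "numeric",
                 betweenAnimalSd = "numeric", shortIsiFraction = "numeric",
                 duration = "numeric", nAnimals = "integer",
                 stimulation = "list"))

setValidity("EphysPreset", function(object) {
  if (object@groupMeanRate <= 0) return("groupMeanRate must be > 0")
  if (object@betweenAnimalSd < 0) return("betweenAnimalSd must be >= 0")
  if (object@shortIsiFraction < 0 || object@shortIsiFraction >= 1)
    return("shortIsiFraction must be in [0, 1)")
  if (object@duration <= 0) return("duration must be > 0")
  if (object@nAnimals < 1L) return("nAnimals must be >= 1")
  TRUE
})

#' Behavior condition preset
#'
#' Ground-truth startle-inhibition levels for the session generator: true
#' GPIAS and PPI percentages, baseline startle amplitude and per-trial
#' coefficient of variation.
#'
#' @slot name preset label.
#' @slot gpiasTrue true gap inhibition (percent, 0-100).
#' @slot ppiTrue true prepulse inhibition (percent, 0-100).
#' @slot baselineAmp baseline startle amplitude (arbitrary force units).
#' @slot trialCv per-trial coefficient of variation (>= 0).
#'
#' @seealso [behaviorPresets()], [genStartleSession()]
#' @export
setClass("BehaviorPreset",
  representation(name = "character", gpiasTrue = "numeric",
                 ppiTrue = "numeric", baselineAmp = "numeric",
                 trialCv = "numeric"))

setValidity("BehaviorPreset", function(object) {
  if (object@gpiasTrue < 0 || object@gpiasTrue > 100)
    return("gpiasTrue must be in [0, 100]")
  if (object@ppiTrue < 0 || object@ppiTrue > 100)
    return("ppiTrue must be in [0, 100]")
  if (object@baselineAmp <= 0) return("baselineAmp must be > 0")
  if (object@trialCv < 0) return("trialCv must be >= 0")
  TRUE
})

#' Inter-spike-interval mixture parameters
#'
#' Parameters of the generative ISI model: a refractory offset plus a
#' two-component mixture of a Gamma "burst" component and an exponential
#' "tonic" component. All time constants are in milliseconds.
#'
#' @slot burstWeight mixture weight of the burst component, in [0, 1].
#' @slot burstShape Gamma shape of the burst component.
#' @slot burstMean Gamma mean of the burst component (ms).
#' @slot tonicMean exponential mean of the tonic component (ms).
#' @slot refractory absolute refractory offset (ms).
#'
#' @seealso [solveIsiMixture()], [genSpikeTimes()]
#' @export
setClass("IsiMixtureParams",
  representation(burstWeight = "numeric", burstShape = "numeric",
                 burstMean = "numeric", tonicMean = "numeric",
                 refractory = "numeric"))

setValidity("IsiMixtureParams", function(object) {
  if (object@burstWeight < 0 || object@burstWeight > 1)
    return("burstWeight must be in [0, 1]")
  if (object@burstShape <= 0 || object@burstMean <= 0 ||
      object@tonicMean <= 0 || object@refractory < 0)
    return("time constants must be positive (refractory >= 0)")
  TRUE
})

#' Extracellular spike waveform template
#'
#' Unit-normalized biphasic waveform (dominant trough at -1) sampled at the
#' recording rate, scaled by `peakAmplitude` when embedded in a trace.
#'
#' @slot waveform numeric samples, min exactly -1.
#' @slot fs sampling rate (Hz).
#' @slot peakAmplitude trough amplitude in microvolts (negative).
#' @slot troughIndex sample index of the trough within the waveform.
#'
#' @seealso [spikeTemplate()], [genVoltage()]
#' @export
setClass("SpikeTemplate",
  representation(waveform = "numeric", fs = "numeric",
                 peakAmplitude = "numeric", troughIndex = "integer"))

setValidity("SpikeTemplate", function(object) {
  w <- object@waveform
  if (!length(w)) return("empty waveform")
  if (abs(min(w) + 1) > 1e-9) return("waveform must be normalized to min -1")
  if (max(abs(w)) > 1 + 1e-9 || -min(w) <= max(w))
    return("dominant extremum must be the negative trough")
  if (object@peakAmplitude >= 0)
    return("peakAmplitude must be negative (negative-going spikes)")
  TRUE
})

#' Ground-truth spike times
#'
#' Spike times drawn from a known ISI mixture, kept alongside the synthetic
#' recording they were embedded in so detection can be scored exactly.
#'
#' @slot times spike times (s), strictly increasing.
#' @slot trueRate the target firing rate (Hz) of the generating mixture.
#' @slot duration recording duration (s).
#' @slot presetName label of the originating preset ("" when none).
#' @slot seed integer seed that produced the draw.
#'
#' @seealso [genSpikeTimes()], [matchSpikeTimes()]
#' @export
setClass("GroundTruthSpikes",
  representation(times = "numeric", trueRate = "numeric",
                 duration = "numeric", presetName = "character",
                 seed = "integer"))

setValidity("GroundTruthSpikes", function(object) {
  t <- object@times
  if (length(t) > 1L && any(diff(t) <= 0))
    return("times must be strictly increasing")
  if (length(t) && (t[1L] < 0 || t[length(t)] > object@duration))
    return("times must lie within [0, duration]")
  TRUE
})
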