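#' @include AllClasses.R isi-mixture.R presets.R
NULL

#' Biphasic extracellular spike template
#'
#' Difference-of-Gaussians waveform: a sharp negative trough followed by a
#' slower positive rebound, the typical extracellular action-potential
#' shape. The waveform is normalized so its trough is exactly -1; the
#' amplitude in microvolts is applied when the template is embedded.
#'
#' @param fs sampling rate in Hz (default 60000).
#' @param peakAmplitude trough amplitude in microvolts, negative
#'   (default -80).
#' @param spanMs total sampled support in ms (default 1.2). The effective
#'   support (samples above 5 percent of the trough) is ~0.8 ms.
#' @return A [SpikeTemplate-class].
#' @examples
#' tpl <- spikeTemplate()
#' length(tpl@waveform) / tpl@fs * 1000  # ~1.2 ms
#' @export
spikeTemplate <- function(fs = 60000, peakAmplitude = -80, spanMs = 1.2) {
  t <- seq(-spanMs / 3, 2 * spanMs / 3, by = 1000 / fs)  # ms
  w <- -(exp(-0.5 * (t / 0.10)^2) - 0.45 * exp(-0.5 * ((t - 0.25) / 0.18)^2))
  w <- w / abs(min(w))
  new("SpikeTemplate", waveform = w, fs = fs,
      peakAmplitude = peakAmplitude, troughIndex = which.min(w))
}

#' Synthesize a voltage trace from ground-truth spikes
#'
#' Embeds one template instance per spike (trough centered at the spike
#' time) in additive Gaussian noise. Overlapping templates are summed.
#'
#' @param spikes a [GroundTruthSpikes-class].
#' @param template a [SpikeTemplate-class] (default [spikeTemplate()]).
#' @param noiseSd noise standard deviation in microvolts (default 10, i.e.
#'   peak SNR 8 with the default -80 uV template).
#' @param fs sampling rate in Hz (default 60000).
#' @param seed integer seed for the noise.
#' @param meta extra metadata stored on the recording.
#' @return A [RawRecording-class] in microvolts.
#' @export
genVoltage <- function(spikes, template = spikeTemplate(fs = fs),
                       noiseSd = 10, fs = 60000, seed = 1, meta = list()) {
  stopifnot(is(spikes, "GroundTruthSpikes"), is(template, "SpikeTemplate"))
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (template@fs != fs) stop("template and recording sampling rates differ")
  n <- round(spikes@duration * fs)
  tw <- template@waveform * abs(template@peakAmplitude)  # trough -> peakAmplitude
  lw <- length(tw)
  x <- .withSeed(seed, if (noiseSd > 0) stats::rnorm(n, 0, noiseSd)
                 else numeric(n))
  centers <- round(spikes@times * fs) + 1L
  starts <- centers - template@troughIndex + 1L
  for (s in starts) {
    i0 <- max(1L, s); i1 <- min(n, s + lw - 1L)
    if (i0 <= i1)
      x[i0:i1] <- x[i0:i1] + tw[(i0 - s + 1L):(i1 - s + 1L)]
  }
  rawRecording(x, fs, c(list(units = "uV", noiseSd = noiseSd,
                             preset = spikes@presetName,
                             seed = as.integer(seed), filtered = FALSE),
                        meta))
}

#' Generate a synthetic group of animals for one condition
#'
#' Draws one true firing rate per animal from
#' Normal(groupMeanRate, betweenAnimalSd) truncated at 0.5 Hz, solves the
#' ISI mixture per animal for the preset's short-ISI fraction, samples the
#' spike times, and (optionally) synthesizes the voltage trace. Per-animal
#' seeds are `masterSeed * 1000 + animal` (noise seeds offset by 500), so
#' the whole group is a pure function of (preset, masterSeed).
#'
#' @param preset an [EphysPreset-class].
#' @param masterSeed integer master seed.
#' @param noiseSd noise SD in microvolts (default 10).
#' @param snr peak signal-to-noise ratio (template trough = snr * noiseSd,
#'   default 8).
#' @param fs sampling rate in Hz (default 60000).
#' @param voltage if FALSE, only ground-truth spikes are generated
#'   (fast path for rate-level simulations).
#' @param burstShape,burstMean,refractory ISI mixture constants
#'   (see [solveIsiMixture()]).
#' @return List with one element per animal, each a list with components
#'   `truth` ([GroundTruthSpikes-class]) and `recording`
#'   ([RawRecording-class] or NULL when `voltage = FALSE`).
#' @export
genGroup <- function(preset, masterSeed, noiseSd = 10, snr = 8,
                     fs = 60000, voltage = TRUE, burstShape = 2,
                     burstMean = 3, refractory = 1) {
  stopifnot(is(preset, "EphysPreset"))
  nA <- preset@nAnimals
  rates <- .withSeed(masterSeed, {
    r <- stats::rnorm(nA, preset@groupMeanRate, preset@betweenAnimalSd)
    while (any(r < 0.5))
      r[r < 0.5] <- stats::rnorm(sum(r < 0.5), preset@groupMeanRate,
                                 preset@betweenAnimalSd)
    r
  })
  tpl <- spikeTemplate(fs = fs, peakAmplitude = -snr * noiseSd)
  lapply(seq_len(nA), function(i) {
    mix <- solveIsiMixture(rates[i], preset@shortIsiFraction,
                           burstShape = burstShape, burstMean = burstMean,
                           refractory = refractory)
    truth <- genSpikeTimes(mix, preset@duration,
                           .deriveSeed(masterSeed, i), preset@name)
    rec <- if (voltage)
      genVoltage(truth, tpl, noiseSd = noiseSd, fs = fs,
                 seed = .deriveSeed(masterSeed, 500 + i),
                 meta = list(animal = i, preset = preset@name))
    list(truth = truth, recording = rec, trueRate = rates[i], animal = i)
  })
}

.dampedStartleWave <- function(amplitude, fs, durationS = 0.15,
                               freq = 40, tau = 0.8) {
  t <- seq(0, durationS, by = 1 / fs)
  (amplitude / 2) * sin(2 * pi * freq * t) * exp(-t / tau)
}

#' Generate a synthetic startle session
#'
#' Builds one full session for a behavior preset: a gap-detection block of
#' 16 gap + 16 no-gap trials and a prepulse block of 15 pulse + 10 prepulse
#' + 8 no-stimulus trials. No-gap and pulse amplitudes are
#' `baselineAmp * (1 + trialCv * eps)` with standard-normal `eps`; gap and
#' prepulse amplitudes are additionally scaled by `(1 - gpiasTrue/100)` and
#' `(1 - ppiTrue/100)`; no-stimulus trials have near-zero amplitude.
#' Negative draws are clipped at 0 (with a message). Optionally each trial
#' carries a damped-sinusoid platform waveform whose peak-to-peak equals
#' the trial amplitude to within ~2 percent, so peak-to-peak extraction can
#' be exercised.
#'
#' @param preset a [BehaviorPreset-class].
#' @param seed integer seed.
#' @param counts named integer vector of trial counts per type.
#' @param withWaveforms attach per-trial waveforms (default FALSE).
#' @param waveformFs waveform sampling rate in Hz (default 1000).
#' @return A [StartleSession-class].
#' @export
genStartleSession <- function(preset, seed,
                              counts = c(gap = 16L, no_gap = 16L,
                                         pulse = 15L, prepulse = 10L,
                                         no_stim = 8L),
                              withWaveforms = FALSE, waveformFs = 1000) {
  stopifnot(is(preset, "BehaviorPreset"),
            all(.startleTypes %in% names(counts)))
  .withSeed(seed, {
    scale <- c(gap = 1 - preset@gpiasTrue / 100, no_gap = 1,
               pulse = 1, prepulse = 1 - preset@ppiTrue / 100)
    mkBlock <- function(types, block) {
      types <- sample(rep(names(types), types))  # shuffle within block
      amp <- vapply(types, function(ty) {
        if (ty == "no_stim")
          preset@baselineAmp * 0.01 * abs(stats::rnorm(1))
        else
          preset@baselineAmp * scale[[ty]] *
            (1 + preset@trialCv * stats::rnorm(1))
      }, numeric(1))
      data.frame(block = block, trial_type = types, amplitude = amp,
                 stringsAsFactors = FALSE)
    }
    tr <- rbind(mkBlock(counts[c("gap", "no_gap")], "gpias"),
                mkBlock(counts[c("pulse", "prepulse", "no_stim")], "ppi"))
    if (any(tr$amplitude < 0)) {
      message(sum(tr$amplitude < 0), " negative amplitude draw(s) clipped at 0")
      tr$amplitude <- pmax(tr$amplitude, 0)
    }
    tr <- cbind(trial_index = seq_len(nrow(tr)), tr)
    rownames(tr) <- NULL
    wv <- if (withWaveforms)
      lapply(tr$amplitude, .dampedStartleWave, fs = waveformFs)
    else list()
    new("StartleSession", trials = tr, waveforms = wv,
        waveformFs = if (withWaveforms) waveformFs else NA_real_,
        meta = list(preset = preset@name, seed = as.integer(seed)))
  })
}
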