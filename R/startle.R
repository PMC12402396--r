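#' @include AllClasses.R
NULL

#' Peak-to-peak response amplitude
#'
#' Max minus min of a platform waveform inside the response window, the
#' standard offline startle-amplitude measure.
#'
#' @param waveform numeric force samples.
#' @param fs sampling rate in Hz.
#' @param window numeric `c(t0, t1)` in seconds relative to waveform start
#'   (default `c(0, 0.1)`, i.e. 100 ms from pulse onset).
#' @return Non-negative amplitude.
#' @examples
#' peakToPeak(sin(2 * pi * 10 * seq(0, 0.1, by = 1e-3)), 1000)  # 2
#' @export
peakToPeak <- function(waveform, fs, window = c(0, 0.1)) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  i0 <- max(1L, floor(window[1] * fs) + 1L)
  i1 <- min(length(waveform), ceiling(window[2] * fs) + 1L)
  if (i0 > i1 || i0 > length(waveform)) stop("empty response window")
  seg <- waveform[i0:i1]
  max(seg) - min(seg)
}

.avgAmp <- function(session, type) {
  tr <- session@trials
  a <- tr$amplitude[tr$trial_type == type]
  if (!length(a)) stop(sprintf("session has no '%s' trials", type))
  mean(a)
}

#' Gap prepulse inhibition of the acoustic startle (GPIAS)
#'
#' `(1 - avgGap / avgNoGap) * 100`: percent reduction of the mean startle
#' amplitude when a silent gap precedes the pulse. A ratio of means, not a
#' mean of per-trial ratios. Deficient gap inhibition is the behavioral
#' proxy for tinnitus.
#'
#' @param session a [StartleSession-class] containing gap and no-gap trials.
#' @return GPIAS in percent (at most 100; negative if facilitation occurs).
#' @export
gpiasIndex <- function(session) {
  stopifnot(is(session, "StartleSession"))
  avgNoGap <- .avgAmp(session, "no_gap")
  if (avgNoGap == 0) stop("GPIAS undefined: mean no-gap amplitude is 0")
  (1 - .avgAmp(session, "gap") / avgNoGap) * 100
}

#' Prepulse inhibition of the acoustic startle (PPI)
#'
#' `(1 - avgPrepulse / avgStartle) * 100`: percent reduction of the mean
#' startle amplitude when a soft prepulse precedes the pulse. Intact PPI
#' controls for hearing integrity.
#'
#' @param session a [StartleSession-class] containing pulse and prepulse
#'   trials.
#' @return PPI in percent.
#' @export
ppiIndex <- function(session) {
  stopifnot(is(session, "StartleSession"))
  avgStartle <- .avgAmp(session, "pulse")
  if (avgStartle == 0) stop("PPI undefined: mean pulse amplitude is 0")
  (1 - .avgAmp(session, "prepulse") / avgStartle) * 100
}

#' Summarize a startle session
#'
#' @param session a [StartleSession-class].
#' @return Named list: `gpias`, `ppi` (percent; NA when the corresponding
#'   block is absent), the four block mean amplitudes, and the no-stimulus
#'   motion baseline (no-stimulus trials enter no index).
#' @export
behaviorSummary <- function(session) {
  tr <- session@trials
  has <- function(ty) any(tr$trial_type == ty)
  list(
    gpias = if (has("gap") && has("no_gap")) gpiasIndex(session) else NA_real_,
    ppi = if (has("pulse") && has("prepulse")) ppiIndex(session) else NA_real_,
    avgGap = if (has("gap")) .avgAmp(session, "gap") else NA_real_,
    avgNoGap = if (has("no_gap")) .avgAmp(session, "no_gap") else NA_real_,
    avgPrepulse = if (has("prepulse")) .avgAmp(session, "prepulse") else NA_real_,
    avgStartle = if (has("pulse")) .avgAmp(session, "pulse") else NA_real_,
    noStimBaseline = if (has("no_stim")) .avgAmp(session, "no_stim") else NA_real_)
}
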