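#' @include AllClasses.R
NULL

#' Robust noise-level estimate (MAD)
#'
#' Median absolute deviation about the median (default), the robust noise
#' estimator standard in spike thresholding. The literal "mean absolute
#' deviation about the mean" reading is available via `center = "mean"`.
#'
#' @param x numeric vector.
#' @param center "median" (default) or "mean".
#' @return Non-negative scalar; raw (unscaled) absolute deviation. Multiply
#'   by 1.4826 for a normal-consistent SD estimate.
#' @examples
#' madEstimate(c(1, 1, 2, 2, 4))  # 1
#' @export
madEstimate <- function(x, center = c("median", "mean")) {
  if (!length(x)) stop("empty input")
  center <- match.arg(center)
  if (center == "median") stats::mad(x, constant = 1)
  else mean(abs(x - mean(x)))
}

#' Detect spikes by MAD thresholding
#'
#' Estimates the noise level of a filtered trace by MAD, thresholds at
#' `k` times the (scaled) MAD, and records a spike at the local extremum
#' within `alignmentWindow` ms after each threshold crossing. Crossings
#' within `deadTime` ms of an accepted spike are ignored.
#'
#' @param filtered a band-pass filtered [RawRecording-class].
#' @param k threshold multiplier (default 5).
#' @param polarity "negative" (default; extracellular spikes are
#'   negative-dominant), "positive", or "both".
#' @param deadTime refractory dead time in ms (default 1).
#' @param alignmentWindow extremum search window after a crossing, ms
#'   (default 1).
#' @param madScaling "normal" (default): MAD is scaled by 1.4826 so `k` is
#'   in noise-SD units; "raw": unscaled MAD.
#' @param madCenter passed to [madEstimate()].
#' @return A [SpikeTrain-class] at the recording's sampling rate. A trace
#'   with no crossings yields a valid empty train with a warning.
#' @export
detectSpikes <- function(filtered, k = 5,
                         polarity = c("negative", "positive", "both"),
                         deadTime = 1, alignmentWindow = 1,
                         madScaling = c("normal", "raw"),
                         madCenter = "median") {
  stopifnot(is(filtered, "RawRecording"), k > 0, deadTime >= 0)
  polarity <- match.arg(polarity)
  madScaling <- match.arg(madScaling)
  x <- filtered@samples
  fs <- filtered@fs
  n <- length(x)
  noise <- madEstimate(x, madCenter) *
    if (madScaling == "normal") 1.4826 else 1
  if (noise == 0) stop("degenerate noise estimate (MAD = 0)")
  thr <- k * noise
  wAlign <- max(0L, round(alignmentWindow / 1000 * fs))

  alignOn <- function(sig) {               # sig: trace with events negative
    below <- sig < -thr
    cr <- which(below & !c(FALSE, below[-n]))
    if (!length(cr)) return(integer(0))
    off <- 0:wAlign
    idx <- outer(cr, off, "+")
    idx[idx > n] <- n
    vals <- matrix(sig[idx], nrow = length(cr))
    cr + off[max.col(-vals, ties.method = "first")]
  }

  cand <- switch(polarity,
    negative = alignOn(x),
    positive = alignOn(-x),
    both = sort(unique(c(alignOn(x), alignOn(-x)))))
  cand <- sort(unique(cand))
  if (!length(cand)) {
    warning("no spikes detected")
    return(spikeTrain(numeric(0), fs, n / fs,
                      meta = list(k = k, threshold = thr)))
  }
  # greedy dead-time enforcement
  deadSamp <- deadTime / 1000 * fs
  keep <- logical(length(cand))
  last <- -Inf
  for (i in seq_along(cand)) {
    if (cand[i] - last >= deadSamp || !is.finite(last)) {
      keep[i] <- TRUE
      last <- cand[i]
    }
  }
  spikeTrain((cand[keep] - 1) / fs, fs, n / fs,
             meta = list(k = k, threshold = thr, polarity = polarity,
                         deadTime = deadTime, madScaling = madScaling))
}

#' Binary 0/1 spike-train representation
#'
#' @param x spike times in seconds, or a [SpikeTrain-class].
#' @param fs sampling rate in Hz (taken from the train when `x` is one).
#' @param duration duration in seconds (likewise).
#' @return Integer 0/1 vector of length `round(duration * fs)`; its sum
#'   equals the number of spikes. Two spikes mapping to one sample is an
#'   error (cannot happen when the detection dead time exceeds `1/fs`).
#' @export
toBinaryTrain <- function(x, fs = NULL, duration = NULL) {
  if (is(x, "SpikeTrain")) {
    if (is.null(fs)) fs <- x@fs
    if (is.null(duration)) duration <- x@duration
    x <- x@times
  }
  stopifnot(!is.null(fs), !is.null(duration))
  n <- round(duration * fs)
  train <- integer(n)
  if (!length(x)) return(train)
  if (any(x < 0 | x > duration)) stop("spike times outside [0, duration]")
  idx <- pmin(pmax(round(x * fs) + 1L, 1L), n)
  if (anyDuplicated(idx))
    stop("two spikes map to the same sample; dead time below 1/fs?")
  train[idx] <- 1L
  train
}

#' Downsample a binary spike train by OR-pooling
#'
#' Each target bin is 1 if any of its `factor` source samples is 1, so no
#' spike is dropped by decimation. Events closer than one target sample
#' collapse into one bin; the collision count is reported via a message.
#'
#' @param train integer 0/1 vector at the source rate.
#' @param factor integer downsampling factor (default 12, i.e.
#'   60 kHz to 5 kHz).
#' @return Integer 0/1 vector of length `ceiling(length(train)/factor)`.
#' @export
downsampleTrain <- function(train, factor = 12L) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be a positive integer")
  n <- length(train)
  if (!n) return(integer(0))
  nOut <- ceiling(n / factor)
  pad <- nOut * factor - n
  if (pad) train <- c(train, integer(pad))
  counts <- colSums(matrix(train, nrow = factor))
  lost <- sum(counts) - sum(counts > 0)
  if (lost > 0)
    message(lost, " spike(s) collided into shared bins during downsampling")
  as.integer(counts > 0)
}

#' Resample a spike train to a lower rate by OR-pooling
#'
#' @param st a [SpikeTrain-class].
#' @param targetFs target sampling rate in Hz; must divide `samplingRate(st)`.
#' @return A [SpikeTrain-class] at `targetFs` with times quantized to the
#'   target sample grid.
#' @export
resampleTrain <- function(st, targetFs = 5000) {
  stopifnot(is(st, "SpikeTrain"))
  ratio <- st@fs / targetFs
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("source sampling rate must be an integer multiple of targetFs")
  bin <- downsampleTrain(toBinaryTrain(st), as.integer(round(ratio)))
  spikeTrain((which(bin == 1L) - 1) / targetFs, targetFs, st@duration,
             meta = st@meta)
}
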