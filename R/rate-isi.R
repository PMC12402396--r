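#' @include AllClasses.R detect.R
NULL

#' Spontaneous firing-rate series (centered boxcar)
#'
#' Converts a binary spike train into an instantaneous firing rate in Hz by
#' a centered 1-s boxcar (a zero-phase moving average). Near the edges the
#' count is normalized by the in-bounds window coverage, so the first and
#' last half-window do not droop.
#'
#' @param x a [SpikeTrain-class], or an integer 0/1 vector (then `fs` is
#'   required).
#' @param window boxcar length in seconds (default 1).
#' @param fs sampling rate in Hz when `x` is a plain vector.
#' @param epoch epoch label stored on the series (default "before").
#' @return A [RateSeries-class] with one rate value per train sample.
#' @examples
#' st <- spikeTrain(seq(0.05, 9.95, by = 0.1), 5000, 10)  # 10 Hz
#' mean(rateValues(sfr(st)))
#' @export
sfr <- function(x, window = 1, fs = NULL, epoch = "before") {
  meta <- list()
  if (is(x, "SpikeTrain")) {
    fs <- x@fs
    meta <- x@meta
    x <- toBinaryTrain(x)
  }
  stopifnot(!is.null(fs), window * fs >= 1)
  n <- length(x)
  L <- round(window * fs)
  if (L > n) stop("window longer than the recording")
  hl <- (L - 1L) %/% 2L
  hr <- L - 1L - hl
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(i - hl, 1L)
  hi <- pmin(i + hr, n)
  counts <- cs[hi + 1L] - cs[lo]
  coverage <- (hi - lo + 1L) / fs
  new("RateSeries", rate = counts / coverage, fs = fs, window = window,
      epoch = epoch, meta = meta)
}

#' Mean firing rate over an interval
#'
#' Arithmetic mean of a rate series over `[t0, t1]`, the per-animal summary
#' used for group comparisons over 5-min epochs.
#'
#' @param series a [RateSeries-class].
#' @param interval numeric `c(t0, t1)` in seconds; NULL (default) for the
#'   whole series.
#' @return Mean rate in Hz.
#' @export
meanSfr <- function(series, interval = NULL) {
  stopifnot(is(series, "RateSeries"))
  t <- timeAxis(series)
  if (is.null(interval)) return(mean(series@rate))
  stopifnot(length(interval) == 2L, interval[1] < interval[2])
  sel <- t >= interval[1] & t <= interval[2]
  if (!any(sel)) stop("empty interval")
  mean(series@rate[sel])
}

#' Inter-spike intervals
#'
#' @param x spike times in seconds, a [SpikeTrain-class] or a
#'   [GroundTruthSpikes-class].
#' @return Successive differences in milliseconds (length n-1); empty for
#'   fewer than two spikes.
#' @examples
#' isis(c(0, 0.002, 0.004, 0.010, 0.030))  # 2 2 6 20 ms
#' @export
isis <- function(x) {
  if (is(x, "SpikeTrain") || is(x, "GroundTruthSpikes")) x <- x@times
  if (length(x) < 2L) return(numeric(0))
  diff(x) * 1000
}

#' Inter-spike-interval histogram
#'
#' Half-open uniform bins `[0, w), [w, 2w), ...` up to `maxIsi`; intervals
#' at or beyond `maxIsi` are counted in a separate overflow count so totals
#' are always conserved.
#'
#' @param isiMs intervals in ms (from [isis()]).
#' @param binWidth bin width in ms (default 5).
#' @param maxIsi upper display edge in ms (default 500).
#' @return List of class `"IsiHistogram"`: `binLo`, `binHi`, `counts`
#'   (integer per bin), `nTotal`, `nOverflow`.
#' @export
isiHistogram <- function(isiMs, binWidth = 5, maxIsi = 500) {
  stopifnot(binWidth > 0, maxIsi > binWidth)
  if (any(isiMs < 0)) stop("negative inter-spike interval: corrupt input")
  nBins <- ceiling(maxIsi / binWidth)
  edges <- (0:nBins) * binWidth
  bin <- floor(isiMs / binWidth) + 1L
  over <- sum(bin > nBins)
  counts <- tabulate(bin[bin <= nBins], nbins = nBins)
  structure(list(binLo = edges[-(nBins + 1L)], binHi = edges[-1L],
                 counts = as.integer(counts),
                 nTotal = length(isiMs), nOverflow = as.integer(over)),
            class = "IsiHistogram")
}

#' @export
print.IsiHistogram <- function(x, ...) {
  cat(sprintf("IsiHistogram: %d ISIs in %d bins of %g ms (+%d overflow)\n",
              x$nTotal, length(x$counts), x$binHi[1] - x$binLo[1],
              x$nOverflow))
  invisible(x)
}

#' Proportion of short inter-spike intervals
#'
#' Fraction of intervals strictly below `threshold` ms, the burst-firing
#' index compared between groups.
#'
#' @param isiMs intervals in ms.
#' @param threshold short-ISI threshold in ms (default 5; an interval of
#'   exactly 5 ms is not short).
#' @return Proportion in [0, 1].
#' @export
shortIsiFraction <- function(isiMs, threshold = 5) {
  if (!length(isiMs)) stop("short-ISI fraction undefined for an empty ISI list")
  mean(isiMs < threshold)
}
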