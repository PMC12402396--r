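#' @include AllClasses.R
NULL

#' Band-pass filter specification
#'
#' @param low low cutoff in Hz (default 300).
#' @param high high cutoff in Hz (default 6000).
#' @param order Butterworth prototype order per pass (default 4; applied
#'   forward and backward, so the magnitude response is 8th order).
#' @return Named list with class `"FilterSpec"`.
#' @export
filterSpec <- function(low = 300, high = 6000, order = 4) {
  stopifnot(low > 0, high > low, order >= 1)
  structure(list(low = low, high = high, order = as.integer(order)),
            class = "FilterSpec")
}

# One zero-phase pass pair: odd-reflect pad, filter forward, filter the
# reversed signal, un-reverse, trim. padLen samples of padding each side.
.zeroPhase <- function(b, a, x, padLen) {
  n <- length(x)
  padLen <- min(padLen, n - 1L)
  head <- 2 * x[1L] - x[(padLen + 1L):2L]
  tail <- 2 * x[n] - x[(n - 1L):(n - padLen)]
  y <- .iirFilter(b, a, c(head, x, tail))
  y <- rev(.iirFilter(b, a, rev(y)))
  y[(padLen + 1L):(padLen + n)]
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass (default 4th-order, 300-6000 Hz) forward
#' and backward so the net phase is zero. Edges are handled by odd
#' reflection padding of three low-cutoff time constants, which keeps
#' startup transients out of the data.
#'
#' @param rec a [RawRecording-class].
#' @param spec a [filterSpec()] (defaults: 300-6000 Hz, order 4).
#' @return A filtered [RawRecording-class] of identical length and
#'   sampling rate, with `filtered = TRUE` and the band recorded in its
#'   metadata.
#' @examples
#' rec <- rawRecording(sin(2 * pi * 1342 * (0:59999) / 60000), 60000)
#' filt <- bandpass(rec)
#' sd(samples(filt)[10000:50000]) / sd(samples(rec)[10000:50000])  # ~1
#' @export
bandpass <- function(rec, spec = filterSpec()) {
  stopifnot(is(rec, "RawRecording"), inherits(spec, "FilterSpec"))
  fs <- rec@fs
  if (spec$high >= fs / 2)
    stop("high cutoff must be below the Nyquist frequency")
  bf <- signal::butter(spec$order, c(spec$low, spec$high) / (fs / 2),
                       type = "pass")
  # settling length from the slowest pole: transients decay below 1e-12
  rmax <- max(Mod(polyroot(rev(bf$a))))
  padLen <- as.integer(max(3 * ceiling(fs / spec$low),
                           ceiling(-log(1e-12) / (1 - rmax))))
  n <- length(rec@samples)
  if (n <= 3L * padLen)
    stop(sprintf(
      "trace too short to filter: %d samples, need > %d (3x settling length)",
      n, 3L * padLen))
  y <- .zeroPhase(bf$b, bf$a, rec@samples, padLen)
  meta <- rec@meta
  meta$filtered <- TRUE
  meta$band <- c(spec$low, spec$high)
  meta$filterOrder <- spec$order
  rawRecording(y, fs, meta)
}
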