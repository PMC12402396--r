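#' @include AllClasses.R
NULL

# Evaluate an expression with a temporary RNG seed, restoring the caller's
# RNG state afterwards so generators are pure functions of (args, seed).
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Derived per-unit seeds stay well inside 32-bit integer range.
.deriveSeed <- function(master, index) {
  as.integer((as.numeric(master) %% 1000000) * 1000 + index)
}

#' Expected short-ISI fraction of an ISI mixture
#'
#' Probability that an inter-spike interval drawn from the mixture (gamma
#' burst / exponential tonic components plus refractory offset) is strictly
#' below `threshold`.
#'
#' @param mix an [IsiMixtureParams-class].
#' @param threshold short-ISI threshold in ms (default 5).
#' @return Probability in [0, 1].
#' @export
mixtureShortFraction <- function(mix, threshold = 5) {
  xc <- threshold - mix@refractory
  if (xc <= 0) return(0)
  fb <- stats::pgamma(xc, shape = mix@burstShape,
                      rate = mix@burstShape / mix@burstMean)
  ft <- 1 - exp(-xc / mix@tonicMean)
  mix@burstWeight * fb + (1 - mix@burstWeight) * ft
}

#' Expected mean ISI of an ISI mixture
#'
#' @param mix an [IsiMixtureParams-class].
#' @return Mean inter-spike interval in ms (refractory offset included).
#' @export
mixtureMeanIsi <- function(mix) {
  mix@refractory + mix@burstWeight * mix@burstMean +
    (1 - mix@burstWeight) * mix@tonicMean
}

#' Solve the ISI mixture for a target rate and short-ISI fraction
#'
#' Inverts the generative ISI model: given a target firing rate and a target
#' proportion of intervals below `threshold` ms, finds the burst-component
#' weight `w` and the tonic exponential mean such that the mixture's mean
#' ISI equals `1000/targetRate` ms and its short-ISI probability equals
#' `targetShortFraction`, both to 1e-6 relative tolerance. The burst
#' component (gamma) is held fixed.
#'
#' @param targetRate target firing rate in Hz.
#' @param targetShortFraction target P(ISI < threshold), in [0, 1).
#' @param burstShape gamma shape of the burst component (default 2).
#' @param burstMean gamma mean of the burst component in ms (default 3).
#' @param refractory absolute refractory offset in ms (default 1).
#' @param threshold short-ISI threshold in ms (default 5).
#' @return An [IsiMixtureParams-class].
#' @examples
#' mix <- solveIsiMixture(15.11, 0.2489)
#' mixtureShortFraction(mix)   # 0.2489
#' 1000 / mixtureMeanIsi(mix)  # 15.11 Hz
#' @export
solveIsiMixture <- function(targetRate, targetShortFraction,
                            burstShape = 2, burstMean = 3,
                            refractory = 1, threshold = 5) {
  stopifnot(targetRate > 0, targetShortFraction >= 0,
            targetShortFraction < 1, burstShape > 0, burstMean > 0,
            refractory >= 0)
  meanIsi <- 1000 / targetRate
  if (meanIsi <= refractory)
    stop("1/targetRate must exceed the refractory period")
  M <- meanIsi - refractory          # required mean of the stochastic part
  xc <- threshold - refractory
  if (xc <= 0)
    stop("short-ISI threshold must exceed the refractory period")
  fb <- stats::pgamma(xc, shape = burstShape, rate = burstShape / burstMean)
  tonicAt <- function(w) (M - w * burstMean) / (1 - w)
  fracAt <- function(w) {
    m <- tonicAt(w)
    w * fb + (1 - w) * (1 - exp(-xc / m))
  }
  # largest admissible w: tonic mean must stay positive
  wMax <- if (burstMean >= M) M / burstMean - 1e-12 else 1 - 1e-9
  lo <- fracAt(0)
  hi <- if (burstMean >= M) fracAt(wMax) else fb
  rng <- sort(c(lo, hi))
  if (targetShortFraction < rng[1] - 1e-12 ||
      targetShortFraction > rng[2] + 1e-12)
    stop(sprintf(
      "infeasible short-ISI target %.6f: attainable interval is [%.6f, %.6f] for rate %.4g Hz with this burst component",
      targetShortFraction, rng[1], rng[2], targetRate))
  w <- if (abs(targetShortFraction - lo) < 1e-14) 0
  else if (abs(targetShortFraction - fracAt(wMax)) < 1e-14) wMax
  else stats::uniroot(function(w) fracAt(w) - targetShortFraction,
                      c(0, wMax), tol = 1e-14)$root
  # exact boundary: pure burst is only mean-consistent when r + B = 1/rate
  if (abs(burstMean - M) < 1e-9 * M &&
      abs(targetShortFraction - fb) < 1e-12)
    w <- 1
  m <- if (w >= 1) M else tonicAt(w)
  new("IsiMixtureParams", burstWeight = w, burstShape = burstShape,
      burstMean = burstMean, tonicMean = m, refractory = refractory)
}

#' Draw inter-spike intervals from an ISI mixture
#'
#' @param mix an [IsiMixtureParams-class].
#' @param n number of intervals.
#' @param seed optional integer seed (caller RNG state is preserved).
#' @return Numeric vector of `n` intervals in ms.
#' @export
drawIsis <- function(mix, n, seed = NULL) {
  draw <- function() {
    burst <- stats::runif(n) < mix@burstWeight
    x <- numeric(n)
    nb <- sum(burst)
    if (nb) x[burst] <- stats::rgamma(nb, shape = mix@burstShape,
                                      rate = mix@burstShape / mix@burstMean)
    if (n - nb) x[!burst] <- stats::rexp(n - nb, rate = 1 / mix@tonicMean)
    mix@refractory + x
  }
  if (is.null(seed)) draw() else .withSeed(seed, draw())
}

#' Generate ground-truth spike times from an ISI mixture
#'
#' Samples a renewal process with the mixture's ISI law until `duration`
#' seconds are covered. Deterministic for a fixed (mix, duration, seed).
#'
#' @param mix an [IsiMixtureParams-class].
#' @param duration recording duration in seconds.
#' @param seed integer seed.
#' @param presetName label stored on the result.
#' @return A [GroundTruthSpikes-class].
#' @export
genSpikeTimes <- function(mix, duration, seed, presetName = "") {
  stopifnot(duration > 0)
  rate <- 1000 / mixtureMeanIsi(mix)    # Hz
  .withSeed(seed, {
    times <- numeric(0)
    t0 <- 0
    repeat {
      need <- max(64, ceiling((duration - t0) * rate * 1.25 +
                                6 * sqrt(duration * rate + 1)))
      isis <- drawIsis(mix, need)
      chunk <- t0 + cumsum(isis) / 1000
      times <- c(times, chunk)
      t0 <- times[length(times)]
      if (t0 > duration) break
    }
    times <- times[times <= duration]
    new("GroundTruthSpikes", times = times, trueRate = rate,
        duration = duration, presetName = presetName,
        seed = as.integer(seed))
  })
}
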