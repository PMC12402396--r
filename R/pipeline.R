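#' @include preprocess.R detect.R rate-isi.R synthesize.R
NULL

#' Match detected against ground-truth spike times
#'
#' Greedy one-to-one matching of two sorted spike-time lists within a
#' tolerance window, for scoring detection against a known embedding.
#'
#' @param detected numeric detected times (s) or a [SpikeTrain-class].
#' @param truth numeric true times (s) or a [GroundTruthSpikes-class].
#' @param tol matching window in seconds (default 1e-3, i.e. +/-1 ms).
#' @return List: `nMatched`, `nMissed`, `nFalse`, `recall`,
#'   `falseFraction` (false positives / true spikes), `timingError`
#'   (signed detected - true, seconds, one per match).
#' @export
matchSpikeTimes <- function(detected, truth, tol = 1e-3) {
  if (is(detected, "SpikeTrain")) detected <- detected@times
  if (is(truth, "GroundTruthSpikes")) truth <- truth@times
  i <- 1L; j <- 1L
  nD <- length(detected); nT <- length(truth)
  err <- numeric(0)
  while (i <= nT && j <= nD) {
    d <- detected[j] - truth[i]
    if (abs(d) <= tol) {
      err <- c(err, d)
      i <- i + 1L; j <- j + 1L
    } else if (d < 0) j <- j + 1L else i <- i + 1L
  }
  nM <- length(err)
  list(nMatched = nM, nMissed = nT - nM, nFalse = nD - nM,
       recall = if (nT) nM / nT else NA_real_,
       falseFraction = if (nT) (nD - nM) / nT else NA_real_,
       timingError = err)
}

#' Raw trace to spikes, rate series and ISI summaries
#'
#' The per-recording analysis chain: zero-phase band-pass ([bandpass()]),
#' MAD-threshold spike detection ([detectSpikes()]), downsampling of the
#' binary train from the acquisition rate to `trainFs` ([resampleTrain()]),
#' 1-s boxcar rate series ([sfr()]) and ISI summaries.
#'
#' @param rec a raw [RawRecording-class].
#' @param spec a [filterSpec()].
#' @param k,polarity,deadTime,madScaling passed to [detectSpikes()].
#' @param trainFs spike-train representation rate in Hz (default 5000).
#' @param window boxcar window in seconds (default 1).
#' @param epoch epoch label for the rate series.
#' @return List: `spikes` ([SpikeTrain-class] at the acquisition rate),
#'   `train` ([SpikeTrain-class] at `trainFs`), `rate`
#'   ([RateSeries-class]), `meanRate` (Hz), `isiMs`, `shortFraction`,
#'   `nSpikes`.
#' @export
processRecording <- function(rec, spec = filterSpec(), k = 5,
                             polarity = "negative", deadTime = 1,
                             madScaling = "normal", trainFs = 5000,
                             window = 1, epoch = "before") {
  filt <- bandpass(rec, spec)
  spikes <- detectSpikes(filt, k = k, polarity = polarity,
                         deadTime = deadTime, madScaling = madScaling)
  train <- resampleTrain(spikes, trainFs)
  rate <- sfr(train, window = window, epoch = epoch)
  isiMs <- isis(spikes)
  list(spikes = spikes, train = train, rate = rate,
       meanRate = meanSfr(rate),
       isiMs = isiMs,
       shortFraction = if (length(isiMs)) shortIsiFraction(isiMs)
                       else NA_real_,
       nSpikes = nSpikes(spikes))
}

#' Generate and analyze a whole synthetic group
#'
#' Streams [genGroup()] animal by animal through [processRecording()],
#' discarding each voltage trace after detection so a full 7-animal,
#' 300-s group fits comfortably in memory. Ground truth is retained and
#' scored with [matchSpikeTimes()].
#'
#' @param preset an [EphysPreset-class].
#' @param masterSeed integer master seed.
#' @param noiseSd,snr,fs generator settings (see [genGroup()]).
#' @param epoch epoch label ("before"/"after") for the rate series.
#' @param ... further arguments to [processRecording()].
#' @return List of class `"GroupPipelineResult"`: `preset`, `animals`
#'   (per-animal lists: `truth`, `result` from [processRecording()],
#'   `match`, `trueRate`), and `summary`, a data.frame with one row per
#'   animal (`animal`, `trueRate`, `meanRate`, `nTrue`, `nDetected`,
#'   `recall`, `falseFraction`, `shortFraction`).
#' @export
runGroupPipeline <- function(preset, masterSeed, noiseSd = 10, snr = 8,
                             fs = 60000, epoch = "before", ...) {
  stopifnot(is(preset, "EphysPreset"))
  rates <- .withSeed(masterSeed, {
    r <- stats::rnorm(preset@nAnimals, preset@groupMeanRate,
                      preset@betweenAnimalSd)
    while (any(r < 0.5))
      r[r < 0.5] <- stats::rnorm(sum(r < 0.5), preset@groupMeanRate,
                                 preset@betweenAnimalSd)
    r
  })
  tpl <- spikeTemplate(fs = fs, peakAmplitude = -snr * noiseSd)
  animals <- lapply(seq_len(preset@nAnimals), function(i) {
    mix <- solveIsiMixture(rates[i], preset@shortIsiFraction)
    truth <- genSpikeTimes(mix, preset@duration,
                           .deriveSeed(masterSeed, i), preset@name)
    rec <- genVoltage(truth, tpl, noiseSd = noiseSd, fs = fs,
                      seed = .deriveSeed(masterSeed, 500 + i),
                      meta = list(animal = i, preset = preset@name))
    res <- processRecording(rec, epoch = epoch, ...)
    rm(rec)
    list(truth = truth, result = res,
         match = matchSpikeTimes(res$spikes, truth), trueRate = rates[i])
  })
  summary <- data.frame(
    animal = seq_along(animals),
    trueRate = vapply(animals, `[[`, numeric(1), "trueRate"),
    meanRate = vapply(animals, function(a) a$result$meanRate, numeric(1)),
    nTrue = vapply(animals, function(a) nSpikes(a$truth), numeric(1)),
    nDetected = vapply(animals, function(a) a$result$nSpikes, numeric(1)),
    recall = vapply(animals, function(a) a$match$recall, numeric(1)),
    falseFraction = vapply(animals, function(a) a$match$falseFraction,
                           numeric(1)),
    shortFraction = vapply(animals, function(a) a$result$shortFraction,
                           numeric(1)))
  structure(list(preset = preset, animals = animals, summary = summary),
            class = "GroupPipelineResult")
}

#' @export
print.GroupPipelineResult <- function(x, ...) {
  cat(sprintf(
    "GroupPipelineResult '%s': %d animals, mean SFR %.3f Hz (target %.2f), pooled short-ISI %.4f\n",
    x$preset@name, nrow(x$summary), mean(x$summary$meanRate),
    x$preset@groupMeanRate, pooledShortFraction(x)))
  invisible(x)
}

#' Pooled short-ISI fraction of a group pipeline result
#'
#' Fraction of all detected ISIs below `threshold` ms, pooled across the
#' animals of one group (each animal contributes its ISIs, not its
#' per-animal fraction).
#'
#' @param groupResult a `"GroupPipelineResult"` from [runGroupPipeline()].
#' @param threshold short-ISI threshold in ms (default 5).
#' @return Proportion in [0, 1].
#' @export
pooledShortFraction <- function(groupResult, threshold = 5) {
  allIsis <- unlist(lapply(groupResult$animals,
                           function(a) a$result$isiMs))
  shortIsiFraction(allIsis, threshold)
}
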