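test_that("peak-to-peak amplitude extraction", {
  fs <- 1000
  t <- seq(0, 0.1, by = 1 / fs)
  expect_equal(peakToPeak(sin(2 * pi * 10 * t), fs), 2, tolerance = 1e-3)
  expect_equal(peakToPeak(rep(4, 200), fs), 0)
  expect_error(peakToPeak(rep(1, 5), fs, window = c(0.5, 0.6)), "empty")
  # damped sinusoid of initial amplitude A: p2p within 2% of 2A
  wv <- tinnipipe:::.dampedStartleWave(2 * 50, fs)  # initial amplitude 50
  expect_equal(peakToPeak(wv, fs), 100, tolerance = 0.02)
})

test_that("session waveforms round-trip the stored trial amplitudes", {
  bp <- behaviorPreset("t", 44.4, 92.97, trialCv = 0.15)
  s <- genStartleSession(bp, 9, withWaveforms = TRUE)
  tr <- trialTable(s)
  big <- which(tr$amplitude > 1)
  p2p <- vapply(s@waveforms[big], peakToPeak, numeric(1), fs = s@waveformFs)
  expect_equal(p2p, tr$amplitude[big], tolerance = 0.02)
})

test_that("GPIAS and PPI are ratios of means with documented edge cases", {
  mk <- function(gap, nogap, pre, pulse) {
    tr <- data.frame(
      trial_index = seq_len(length(gap) + length(nogap) + length(pre) +
                              length(pulse)),
      block = "x",
      trial_type = rep(c("gap", "no_gap", "prepulse", "pulse"),
                       c(length(gap), length(nogap), length(pre),
                         length(pulse))),
      amplitude = c(gap, nogap, pre, pulse))
    new("StartleSession", trials = tr, waveforms = list(),
        waveformFs = NA_real_, meta = list())
  }
  expect_equal(gpiasIndex(mk(c(3, 5), c(3, 5), 1, 1)), 0)
  expect_equal(gpiasIndex(mk(c(0, 0), c(3, 5), 1, 1)), 100)
  expect_equal(ppiIndex(mk(1, 1, c(2, 2), c(2, 2))), 0)
  expect_equal(ppiIndex(mk(1, 1, c(0, 0), c(2, 2))), 100)
  expect_error(gpiasIndex(mk(1, c(0, 0), 1, 1)), "no-gap")
  expect_error(ppiIndex(mk(1, 1, 1, c(0, 0))), "pulse")
  # scale invariance
  s1 <- mk(c(2, 4), c(6, 10), c(1, 2), c(8, 9))
  s2 <- mk(7 * c(2, 4), 7 * c(6, 10), 7 * c(1, 2), 7 * c(8, 9))
  expect_equal(gpiasIndex(s2), gpiasIndex(s1))
  expect_equal(ppiIndex(s2), ppiIndex(s1))
})

test_that("index estimators are consistent across many sessions", {
  bp <- behaviorPreset("tb", 44.40, 92.97, trialCv = 0.15)
  est <- vapply(1:1000, function(s) {
    ses <- genStartleSession(bp, s)
    c(gpiasIndex(ses), ppiIndex(ses))
  }, numeric(2))
  expect_lt(abs(mean(est[1, ]) - 44.40), 0.5)
  expect_lt(abs(mean(est[2, ]) - 92.97), 0.5)
})

test_that("behaviorSummary reports indices and motion baseline", {
  s <- genStartleSession(behaviorPreset("cb", 41.51, 96.20), 3)
  bs <- behaviorSummary(s)
  expect_equal(bs$gpias, gpiasIndex(s))
  expect_equal(bs$ppi, ppiIndex(s))
  expect_lt(bs$noStimBaseline, 0.05 * bs$avgStartle)
})
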