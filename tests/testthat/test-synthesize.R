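test_that("template is biphasic, negative-dominant, ~1.2 ms support", {
  tpl <- spikeTemplate()
  expect_equal(min(tpl@waveform), -1)
  expect_lt(max(tpl@waveform), 1)
  expect_gt(max(tpl@waveform), 0)      # rebound exists
  expect_equal(length(tpl@waveform) / tpl@fs, 1.2e-3, tolerance = 0.05)
})

test_that("noiseless voltage embeds the template exactly at the spike time", {
  gt <- new("GroundTruthSpikes", times = 1.0, trueRate = 1, duration = 2,
            presetName = "", seed = 1L)
  tpl <- spikeTemplate(peakAmplitude = -80)
  rec <- genVoltage(gt, tpl, noiseSd = 0, seed = 1)
  x <- samples(rec)
  expect_equal(length(x), 120000)
  expect_equal(which.min(x), 60001)          # trough at round(t*fs)+1
  expect_equal(min(x), -80)
  # zeros outside the template support
  expect_equal(sum(abs(x) > 0), sum(tpl@waveform != 0))
  # local negative extrema beyond half peak == spike count
  deep <- which(x < -40)
  expect_equal(sum(diff(c(-10, deep)) > 1) , 1)
})

test_that("group generation is reproducible and respects preset structure", {
  p <- ephysPreset("t", 10, 0, 0.2, duration = 2, nAnimals = 3L)
  g1 <- genGroup(p, 5, voltage = FALSE)
  g2 <- genGroup(p, 5, voltage = FALSE)
  expect_length(g1, 3)
  expect_identical(lapply(g1, function(a) spikeTimes(a$truth)),
                   lapply(g2, function(a) spikeTimes(a$truth)))
  # zero between-animal SD: all true rates equal the group mean
  expect_equal(vapply(g1, `[[`, numeric(1), "trueRate"), rep(10, 3))
})

test_that("drawn per-animal rates are unbiased around the group mean", {
  p <- ephysPreset("cp", 5.17, 1.31, 0.1986, duration = 0.5, nAnimals = 7L)
  rates <- unlist(lapply(1:200, function(s)
    vapply(genGroup(p, s, voltage = FALSE), `[[`, numeric(1), "trueRate")))
  expect_length(rates, 1400)
  expect_lt(abs(mean(rates) - 5.17), 3 * 1.31 / sqrt(1400))
})

test_that("startle sessions have the prescribed trial counts and truth", {
  bp <- behaviorPreset("tb", gpiasTrue = 44.40, ppiTrue = 92.97,
                       trialCv = 0.15)
  s <- genStartleSession(bp, 1)
  counts <- table(trialTable(s)$trial_type)
  expect_equal(counts[["gap"]], 16)
  expect_equal(counts[["no_gap"]], 16)
  expect_equal(counts[["pulse"]], 15)
  expect_equal(counts[["prepulse"]], 10)
  expect_equal(counts[["no_stim"]], 8)
  expect_identical(trialTable(genStartleSession(bp, 1)), trialTable(s))

  # noiseless inversion: estimators return the preset truth exactly
  bp0 <- behaviorPreset("tp", gpiasTrue = 21.20, ppiTrue = 92.97,
                        trialCv = 0)
  s0 <- genStartleSession(bp0, 2)
  expect_equal(gpiasIndex(s0), 21.20)
  expect_equal(ppiIndex(s0), 92.97)
})

test_that("degenerate inhibition levels invert correctly", {
  full <- genStartleSession(behaviorPreset("f", 100, 100, trialCv = 0), 1)
  expect_equal(gpiasIndex(full), 100)
  expect_equal(ppiIndex(full), 100)
  # zero inhibition: estimator unbiased around 0 across seeds
  none <- vapply(1:100, function(s)
    gpiasIndex(genStartleSession(behaviorPreset("z", 0, 0, trialCv = 0.15),
                                 s)), numeric(1))
  expect_lt(abs(mean(none)), 1.5)
})
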