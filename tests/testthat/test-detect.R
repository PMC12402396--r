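test_that("madEstimate matches hand computation and normal quantile", {
  expect_equal(madEstimate(c(1, 1, 2, 2, 4)), 1)
  expect_equal(madEstimate(rep(3, 10)), 0)
  expect_error(madEstimate(numeric(0)), "empty")
  set.seed(2)
  x <- rnorm(1e6, sd = 7)
  expect_equal(madEstimate(x), 0.6745 * 7, tolerance = 0.01)
  expect_equal(madEstimate(x, center = "mean"), sqrt(2 / pi) * 7,
               tolerance = 0.01)
})

test_that("embedded templates are detected at their insertion times", {
  rec <- makeNoisyRecording(2, c(0.5, 1.0, 1.5), noiseSd = 10, peak = -80,
                            seed = 3)
  st <- detectSpikes(bandpass(rec), k = 5)
  expect_equal(nSpikes(st), 3)
  expect_true(all(abs(spikeTimes(st) - c(0.5, 1.0, 1.5)) < 2e-4))
})

test_that("false-positive rate on pure noise stays below 0.5 Hz", {
  rec <- makeNoisyRecording(60, numeric(0), noiseSd = 10, seed = 8)
  st <- suppressWarnings(detectSpikes(bandpass(rec), k = 5))
  expect_lt(nSpikes(st) / 60, 0.5)
})

test_that("detection is scale-equivariant and monotone in k", {
  rec <- makeNoisyRecording(5, seq(0.25, 4.75, by = 0.5), noiseSd = 10,
                            seed = 5)
  filt <- bandpass(rec)
  t1 <- spikeTimes(detectSpikes(filt, k = 5))
  scaled <- rawRecording(10 * samples(filt), samplingRate(filt))
  expect_identical(spikeTimes(detectSpikes(scaled, k = 5)), t1)
  counts <- vapply(c(3, 4, 5, 6, 7), function(k)
    nSpikes(suppressWarnings(detectSpikes(filt, k = k))), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("degenerate traces are rejected, silent traces warn", {
  expect_error(detectSpikes(rawRecording(rep(1, 1000), 60000)),
               "degenerate noise")
  quiet <- makeNoisyRecording(1, numeric(0), noiseSd = 1, seed = 1)
  expect_warning(st <- detectSpikes(bandpass(quiet), k = 20),
                 "no spikes")
  expect_equal(nSpikes(st), 0)
})

test_that("binary trains conserve spike counts and reject collisions", {
  expect_equal(sum(toBinaryTrain(numeric(0), 60000, 1)), 0)
  tr <- toBinaryTrain(1.0, 60000, 2)
  expect_equal(which(tr == 1L), 60001)
  times <- seq(0.05, 299.95, by = 0.2)      # 1500 spikes
  expect_equal(sum(toBinaryTrain(times, 60000, 300)), 1500)
  expect_error(toBinaryTrain(c(0.5, 0.500001), 60000, 1), "same sample")
})

test_that("OR-pooling downsampling preserves well-separated spikes", {
  st <- spikeTrain(seq(0.05, 9.95, by = 0.1), 60000, 10,
                   meta = list())
  tr60 <- toBinaryTrain(st)
  tr5 <- downsampleTrain(tr60, 12)
  expect_equal(sum(tr5), sum(tr60))
  expect_length(tr5, 50000)
  # adversarial collision: indices 1 and 12 share a target bin
  adv <- integer(24); adv[c(1, 12)] <- 1L
  expect_message(out <- downsampleTrain(adv, 12), "collided")
  expect_equal(sum(out), 1)
  expect_equal(downsampleTrain(integer(0), 12), integer(0))
  # resampleTrain round-trips counts
  expect_equal(nSpikes(resampleTrain(st, 5000)), nSpikes(st))
  expect_error(resampleTrain(st, 7000), "integer multiple")
})
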