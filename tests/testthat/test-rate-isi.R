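test_that("boxcar rate series counts correctly", {
  # empty train -> identically zero
  expect_true(all(rateValues(sfr(integer(5000), fs = 5000)) == 0))
  # periodic 10 Hz train: interior within 10 +/- 1 Hz
  st <- spikeTrain(seq(0.05, 19.95, by = 0.1), 5000, 20)
  rs <- sfr(st)
  interior <- rateValues(rs)[5001:95000]
  expect_true(all(abs(interior - 10) <= 1))
  # conservation: mean rate * duration == spike count within 0.5%
  expect_equal(meanSfr(rs) * 20, 200, tolerance = 0.005)
  expect_error(sfr(integer(100), fs = 5000, window = 1), "window longer")
})

test_that("rate conservation holds on a realistic synthetic train", {
  mix <- solveIsiMixture(5.17, 0.1986)
  gt <- genSpikeTimes(mix, 300, seed = 21)
  st <- spikeTrain(spikeTimes(gt), 5000, 300)
  st@times <- (round(st@times * 5000)) / 5000  # snap to grid
  st@times <- unique(st@times)
  rs <- sfr(st)
  expect_equal(meanSfr(rs) * 300, nSpikes(st), tolerance = 0.005)
  # interval mean recovers the true rate within 3 Poisson standard errors
  expect_lt(abs(meanSfr(rs, c(0, 300)) - 5.17), 3 * sqrt(5.17 / 300))
  expect_error(meanSfr(rs, c(400, 500)), "empty")
})

test_that("rate series is shift-invariant away from edges", {
  times <- seq(2, 8, by = 0.2)
  a <- sfr(spikeTrain(times, 5000, 20))
  b <- sfr(spikeTrain(times + 5, 5000, 20))
  # rate of the shifted train at t equals rate of the original at t - 5
  expect_equal(rateValues(b)[40001:60000], rateValues(a)[15001:35000],
               tolerance = 1e-12)
  expect_equal(isis(times + 5), isis(times))
})

test_that("ISIs match hand computation", {
  expect_equal(isis(c(0, 0.002, 0.004, 0.010, 0.030)), c(2, 2, 6, 20))
  expect_identical(isis(0.5), numeric(0))
  expect_identical(isis(numeric(0)), numeric(0))
  mix <- solveIsiMixture(10, 0.22)
  expect_true(all(isis(genSpikeTimes(mix, 10, 1)) > 0))
})

test_that("ISI histogram uses half-open 5 ms bins and conserves totals", {
  h <- isiHistogram(c(2, 2, 6, 20))
  expect_equal(h$counts[1], 2)   # [0,5)
  expect_equal(h$counts[2], 1)   # [5,10)
  expect_equal(h$counts[5], 1)   # [20,25)
  expect_equal(sum(h$counts), 4)
  # boundary: exactly 5 ms falls in [5,10)
  hb <- isiHistogram(5)
  expect_equal(hb$counts[1], 0)
  expect_equal(hb$counts[2], 1)
  # empty input and overflow accounting
  h0 <- isiHistogram(numeric(0))
  expect_equal(h0$nTotal, 0)
  expect_true(all(h0$counts == 0))
  hov <- isiHistogram(c(1, 700))
  expect_equal(hov$nOverflow, 1)
  expect_equal(sum(hov$counts) + hov$nOverflow, hov$nTotal)
  expect_error(isiHistogram(-1), "negative")
})

test_that("short-ISI fraction uses a strict threshold", {
  expect_equal(shortIsiFraction(c(2, 2, 6, 20)), 0.5)
  expect_equal(shortIsiFraction(c(5, 6, 20)), 0)
  expect_error(shortIsiFraction(numeric(0)), "empty")
  # generator calibration: 1e6 draws from the tinnitus baseline mixture
  mix <- solveIsiMixture(15.11, 0.2489)
  expect_equal(shortIsiFraction(drawIsis(mix, 1e6, seed = 31)), 0.2489,
               tolerance = 0.005 / 0.2489)
})
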