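test_that("rank statistics match brute-force oracles on small samples", {
  set.seed(10)
  for (rep in 1:40) {
    nA <- sample(2:8, 1); nB <- sample(2:8, 1)
    # mix continuous and tied-integer cases
    a <- if (rep %% 2) rnorm(nA) else sample(1:4, nA, replace = TRUE)
    b <- if (rep %% 2) rnorm(nB) else sample(1:4, nB, replace = TRUE)
    kw <- kruskalWallis(a, b)
    expect_equal(kw$H, bruteKruskalH(a, b), tolerance = 1e-10)
    expect_equal(rankBiserial(a, b), bruteRankBiserial(a, b),
                 tolerance = 1e-10)
    expect_equal(ksTwoSample(a, b)$D, bruteKsD(a, b), tolerance = 1e-12)
  }
})

test_that("rank statistics are invariant under monotone transforms", {
  set.seed(11)
  a <- rnorm(6); b <- rnorm(7)
  f <- function(x) exp(2 * x) + 3
  expect_equal(kruskalWallis(a, b)$H, kruskalWallis(f(a), f(b))$H)
  expect_equal(rankBiserial(a, b), rankBiserial(f(a), f(b)))
  expect_equal(kruskalWallis(a + 10, b + 10)$H, kruskalWallis(a, b)$H)
})

test_that("degenerate and separated group configurations", {
  expect_equal(kruskalWallis(c(1, 2, 3), c(1, 2, 3))$H, 0)
  expect_equal(kruskalWallis(rep(2, 3), rep(2, 4)), list(H = 0, p = 1))
  expect_equal(rankBiserial(c(10, 11, 12), c(1, 2, 3)), 1)
  expect_equal(rankBiserial(c(1, 2, 3), c(10, 11, 12)), -1)
  expect_equal(rankBiserial(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rankBiserial(c(3, 4, 5), c(1, 2, 6)),
               bruteRankBiserial(c(3, 4, 5), c(1, 2, 6)))
  expect_equal(ksTwoSample(1:5, 1:5)$D, 0)
  expect_equal(ksTwoSample(1:5, 11:15)$D, 1)
})

test_that("effect tiers follow the significance-gated thresholds", {
  expect_equal(classifyEffect(0.6, 0.01), "high")
  expect_equal(classifyEffect(0.9, 0.20), "ns")
  expect_equal(classifyEffect(0.2, 0.01), "medium")   # inclusive at 0.2
  expect_equal(classifyEffect(0.5, 0.01), "high")     # inclusive at 0.5
  expect_equal(classifyEffect(-0.3, 0.01), "medium")  # magnitude-based
  expect_equal(classifyEffect(0.19, 0.04), "low")
  expect_equal(classifyEffect(c(0.6, 0.1), c(0.01, 0.01)),
               c("high", "low"))
})

test_that("chi-square on the 2x2 short-ISI table", {
  expect_equal(chiSqShortIsi(c(20, 80), c(10, 90))$chi2, 3.9216,
               tolerance = 1e-4)
  expect_equal(chiSqShortIsi(c(20, 80), c(10, 90))$chi2,
               bruteChi2(c(20, 80), c(10, 90)), tolerance = 1e-10)
  expect_equal(chiSqShortIsi(c(25, 75), c(50, 150))$chi2, 0)
  # symmetry under row swap
  expect_equal(chiSqShortIsi(c(10, 90), c(20, 80))$chi2,
               chiSqShortIsi(c(20, 80), c(10, 90))$chi2)
  expect_warning(chiSqShortIsi(c(2, 8), c(1, 9)), "expected count")
})

test_that("normality gate routes to the right test", {
  routes <- vapply(1:1000, function(s) {
    set.seed(s)
    compareGroupMeans(rnorm(7), rnorm(7))$testUsed
  }, character(1))
  expect_gt(mean(routes == "unpaired t"), 0.8)
  # heavy-tailed data go nonparametric more often than normal data
  set.seed(1)
  skewed <- replicate(200, compareGroupMeans(exp(rnorm(7, sd = 2)),
                                             exp(rnorm(7, sd = 2)))$testUsed)
  expect_gt(mean(skewed == "Mann-Whitney U"), mean(routes != "unpaired t"))
})

test_that("group comparison has power at the reported group separation", {
  sims <- lapply(1:1000, function(s) {
    set.seed(s)
    compareGroupMeans(rnorm(7, 15.11, 2.64), rnorm(7, 5.17, 1.31))
  })
  p <- vapply(sims, `[[`, numeric(1), "p")
  expect_gte(mean(p < 0.05), 0.99)
  # runs routed to the t-test reach p < 0.001 nearly always; the
  # rank-test route cannot go below ~0.002 at n = 7 vs 7
  tRoute <- vapply(sims, `[[`, character(1), "testUsed") == "unpaired t"
  expect_gte(mean(p[tRoute] < 0.001), 0.95)
})

test_that("paired and degenerate comparisons behave", {
  a <- c(3, 5, 7, 9, 11)
  expect_warning(res <- compareGroupMeans(a, a, paired = TRUE),
                 "degenerate")
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  expect_warning(res2 <- compareGroupMeans(a + 2, a, paired = TRUE),
                 "degenerate")
  expect_equal(res2$p, 0)
  expect_error(compareGroupMeans(1:4, 1:5, paired = TRUE), "equal-length")
  expect_error(compareGroupMeans(1:2, 1:5))
})

test_that("paired spike-count test detects the post-stimulation drop", {
  expect_warning(same <- pairedSpikeCountTest(c(100, 200, 300),
                                              c(100, 200, 300)),
                 "degenerate")
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_warning(shift <- pairedSpikeCountTest(c(10, 20, 30), c(5, 15, 25)),
                 "degenerate")
  expect_equal(shift$p, 0)
  # power: tinnitus-like drop in per-animal counts over 300 s
  sig <- vapply(1:1000, function(s) {
    set.seed(s)
    before <- pmax(rnorm(7, 15.11, 2.64), 0.5) * 300
    after <- pmax(rnorm(7, 6.07, 2.03), 0.5) * 300
    pairedSpikeCountTest(round(before), round(after))$p < 0.05
  }, logical(1))
  expect_gte(mean(sig), 0.99)
})

test_that("timepoint scan controls type-I error and has one row per step", {
  set.seed(42)
  rej <- replicate(200, {
    A <- matrix(rnorm(7 * 10, 5, 1.3), nrow = 7)
    B <- matrix(rnorm(7 * 10, 5, 1.3), nrow = 7)
    mean(timepointScan(A, B)$p < 0.05)
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
  # single-timepoint degenerate grid
  A <- matrix(rnorm(14), nrow = 7)
  expect_equal(nrow(timepointScan(A, A + 1)), 2)
  expect_error(timepointScan(matrix(rnorm(12), 2), matrix(rnorm(10), 2)),
               "timepoints")
})

test_that("timepoint scan separates the hyperactive group from controls", {
  mkGroup <- function(rate, sd, seed) {
    set.seed(seed)
    rates <- pmax(rnorm(7, rate, sd), 0.5)
    lapply(seq_along(rates), function(i) {
      mix <- solveIsiMixture(rates[i], 0.22)
      gt <- genSpikeTimes(mix, 120, seed = seed * 100 + i)
      sfr(spikeTrain(round(spikeTimes(gt) * 5000) / 5000, 5000, 120))
    })
  }
  tinn <- mkGroup(15.11, 2.64, 1)
  ctrl <- mkGroup(5.17, 1.31, 2)
  scan <- timepointScan(tinn, ctrl)
  frac <- mean(scan$p < 0.05 & scan$tier %in% c("medium", "high"))
  expect_gte(frac, 0.9)
  # BH adjustment never lowers p-values
  scanBH <- timepointScan(tinn, ctrl, adjust = "BH")
  expect_true(all(scanBH$p >= scan$p - 1e-12))
})
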