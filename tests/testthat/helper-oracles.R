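# Brute-force statistical oracles, independent of the package's
# implementations (no rank(), kruskal.test() etc. beyond elementary sums).

# midrank of each element of x within pooled vector v
midranks <- function(v) {
  vapply(v, function(xi) sum(v < xi) + (sum(v == xi) + 1) / 2, numeric(1))
}

bruteKruskalH <- function(a, b) {
  v <- c(a, b)
  N <- length(v)
  rk <- midranks(v)
  Ra <- mean(rk[seq_along(a)])
  Rb <- mean(rk[length(a) + seq_along(b)])
  H <- 12 / (N * (N + 1)) *
    (length(a) * (Ra - (N + 1) / 2)^2 + length(b) * (Rb - (N + 1) / 2)^2)
  ties <- table(v)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr == 0) 0 else H / corr
}

bruteRankBiserial <- function(a, b) {
  wins <- 0; losses <- 0
  for (x in a) for (y in b) {
    if (x > y) wins <- wins + 1
    else if (x < y) losses <- losses + 1
    else { wins <- wins + 0.5; losses <- losses + 0.5 }
  }
  (wins - losses) / (length(a) * length(b))
}

bruteKsD <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(vapply(grid, function(g) mean(a <= g) - mean(b <= g),
                 numeric(1))))
}

bruteChi2 <- function(countsA, countsB) {
  m <- rbind(countsA, countsB)
  expd <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - expd)^2 / expd)
}

# tiny filtered-noise recording for detection tests
makeNoisyRecording <- function(durationS, spikeTimesS = numeric(0),
                               noiseSd = 10, peak = -80, fs = 60000,
                               seed = 1) {
  gt <- new("GroundTruthSpikes", times = spikeTimesS, trueRate = NA_real_,
            duration = durationS, presetName = "fixture",
            seed = as.integer(seed))
  genVoltage(gt, spikeTemplate(fs = fs, peakAmplitude = peak),
             noiseSd = noiseSd, fs = fs, seed = seed)
}
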