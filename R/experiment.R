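#' @include pipeline.R startle.R stats.R
NULL

#' Experiment configuration
#'
#' Bundles every knob of the end-to-end synthetic experiment. A master
#' seed is mandatory: all randomness in [runExperiment()] derives from it,
#' so a config fully determines the report.
#'
#' @param masterSeed integer master seed (required).
#' @param nAnimals animals per group (NULL: per-preset default, 7).
#' @param duration recording duration in seconds (NULL: preset default,
#'   300).
#' @param noiseSd,snr generator noise settings.
#' @param k MAD threshold multiplier.
#' @param band band-pass edges in Hz.
#' @param filterOrder Butterworth prototype order.
#' @param window boxcar window (s).
#' @param step timepoint-scan grid step (s).
#' @param nSessions startle sessions per behavior preset.
#' @param presetCatalog optional path to an alternative preset catalog.
#' @param outDir output directory for artifacts (NULL: nothing written).
#' @return Named list with class `"ExperimentConfig"`.
#' @export
experimentConfig <- function(masterSeed, nAnimals = NULL, duration = NULL,
                             noiseSd = 10, snr = 8, k = 5,
                             band = c(300, 6000), filterOrder = 4,
                             window = 1, step = 1, nSessions = 7L,
                             presetCatalog = NULL, outDir = NULL) {
  if (missing(masterSeed) || is.null(masterSeed))
    stop("a master seed is mandatory (reproducibility)")
  structure(list(masterSeed = as.integer(masterSeed), nAnimals = nAnimals,
                 duration = duration, noiseSd = noiseSd, snr = snr, k = k,
                 band = band, filterOrder = filterOrder, window = window,
                 step = step, nSessions = as.integer(nSessions),
                 presetCatalog = presetCatalog, outDir = outDir),
            class = "ExperimentConfig")
}

.writeCsv <- function(df, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  utils::write.csv(df, file.path(dir, name), row.names = FALSE)
}

#' Run the full synthetic experiment
#'
#' Reproduces the complete analysis on synthetic data: for each of the four
#' ephys presets, generates a group of animals and runs the raw-to-rate
#' pipeline ([runGroupPipeline()]); compares per-animal mean rates between
#' and within groups ([compareGroupMeans()], [pairedSpikeCountTest()]);
#' scans rate series per timepoint ([timepointScan()]); compares pooled ISI
#' distributions and short-ISI proportions ([ksTwoSample()],
#' [chiSqShortIsi()]); and computes GPIAS/PPI indices on simulated startle
#' sessions for each behavior preset. Deterministic for a fixed config.
#'
#' The four ephys group master seeds are `masterSeed` offset by 42, 43, 44
#' and 45 (tinnitus_pre, control_pre, tinnitus_post, control_post);
#' behavior session seeds are offset by 1-7 per preset block.
#'
#' @param config an [experimentConfig()].
#' @return List of class `"ExperimentReport"`: `config`, `sfr` (per-animal
#'   summary data.frame across groups), `groupComparisons`,
#'   `timepointTables` (one per phase), `isi` (histograms + comparisons),
#'   `behavior` (per-session indices), `spikeCountTest`, `version`. When
#'   `config$outDir` is set, CSV/JSON artifacts are written there.
#' @export
runExperiment <- function(config) {
  stopifnot(inherits(config, "ExperimentConfig"))
  dir <- config$outDir
  if (!is.null(dir) && !dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  eph <- ephysPresets(config$presetCatalog)
  seedOff <- c(tinnitus_pre = 42L, control_pre = 43L, tinnitus_post = 44L,
               control_post = 45L)
  eph <- eph[names(seedOff)]
  spec <- filterSpec(config$band[1], config$band[2], config$filterOrder)

  groups <- lapply(names(eph), function(nm) {
    p <- eph[[nm]]
    if (!is.null(config$nAnimals)) p@nAnimals <- as.integer(config$nAnimals)
    if (!is.null(config$duration)) p@duration <- config$duration
    runGroupPipeline(p, .deriveSeed(config$masterSeed, seedOff[[nm]]),
                     noiseSd = config$noiseSd, snr = config$snr,
                     epoch = if (grepl("_post$", nm)) "after" else "before",
                     spec = spec, k = config$k, window = config$window)
  })
  names(groups) <- names(eph)

  sfrTab <- do.call(rbind, lapply(names(groups), function(nm) {
    s <- groups[[nm]]$summary
    cbind(preset = nm, s)
  }))
  .writeCsv(sfrTab, dir, "sfr_per_animal.csv")
  if (!is.null(dir))
    for (nm in names(groups)) {
      anims <- groups[[nm]]$animals
      for (i in seq_along(anims))
        .writeCsv(data.frame(spike_time_s = spikeTimes(anims[[i]]$result$spikes)),
                  dir, sprintf("spikes_%s_animal%d.csv", nm, i))
    }

  mr <- lapply(groups, function(g) g$summary$meanRate)
  smallN <- any(vapply(mr, length, integer(1)) < 3L)
  comparisons <- if (smallN) {
    warning("fewer than 3 animals per group: normality-gated comparisons skipped")
    list()
  } else list(
    pre_between = compareGroupMeans(mr$tinnitus_pre, mr$control_pre,
                                    label = "tinnitus vs control (before)"),
    post_between = compareGroupMeans(mr$tinnitus_post, mr$control_post,
                                     label = "tinnitus vs control (after)"),
    tinnitus_within = compareGroupMeans(mr$tinnitus_pre, mr$tinnitus_post,
                                        paired = TRUE,
                                        label = "tinnitus before vs after"),
    control_within = compareGroupMeans(mr$control_pre, mr$control_post,
                                       paired = TRUE,
                                       label = "control before vs after"))

  rateLists <- lapply(groups, function(g)
    lapply(g$animals, function(a) a$result$rate))
  scans <- list(
    before = timepointScan(rateLists$tinnitus_pre, rateLists$control_pre,
                           step = config$step),
    after = timepointScan(rateLists$tinnitus_post, rateLists$control_post,
                          step = config$step))
  .writeCsv(scans$before, dir, "timepoint_stats_before.csv")
  .writeCsv(scans$after, dir, "timepoint_stats_after.csv")

  pooled <- lapply(groups, function(g)
    unlist(lapply(g$animals, function(a) a$result$isiMs)))
  shortCounts <- lapply(pooled, function(v)
    c(short = sum(v < 5), nonShort = sum(v >= 5)))
  isi <- list(
    histograms = lapply(pooled, isiHistogram),
    ks = list(
      before = ksTwoSample(pooled$tinnitus_pre, pooled$control_pre),
      after = ksTwoSample(pooled$tinnitus_post, pooled$control_post)),
    chi2 = list(
      before = chiSqShortIsi(shortCounts$tinnitus_pre,
                             shortCounts$control_pre),
      after = chiSqShortIsi(shortCounts$tinnitus_post,
                            shortCounts$control_post)),
    shortFractions = vapply(groups, pooledShortFraction, numeric(1)))
  if (!is.null(dir))
    for (nm in names(isi$histograms)) {
      h <- isi$histograms[[nm]]
      .writeCsv(data.frame(bin_lo_ms = h$binLo, bin_hi_ms = h$binHi,
                           count = h$counts),
                dir, sprintf("isi_hist_%s.csv", nm))
    }

  spikeCountTest <- pairedSpikeCountTest(
    groups$tinnitus_pre$summary$nDetected,
    groups$tinnitus_post$summary$nDetected)

  beh <- behaviorPresets(config$presetCatalog)
  behavior <- do.call(rbind, lapply(names(beh), function(nm) {
    idx <- seq_len(config$nSessions)
    rows <- lapply(idx, function(i) {
      s <- genStartleSession(beh[[nm]],
                             .deriveSeed(config$masterSeed,
                                         100L + match(nm, names(beh)) * 10L + i))
      data.frame(preset = nm, session = i,
                 gpias = gpiasIndex(s), ppi = ppiIndex(s))
    })
    do.call(rbind, rows)
  }))
  .writeCsv(behavior, dir, "behavior_indices.csv")

  report <- structure(list(
    config = unclass(config), sfr = sfrTab,
    groupComparisons = comparisons, timepointTables = scans, isi = isi,
    spikeCountTest = spikeCountTest, behavior = behavior,
    version = as.character(utils::packageVersion("tinnipipe"))),
    class = "ExperimentReport")
  if (!is.null(dir)) {
    json <- list(
      config = unclass(config), version = report$version,
      sfr_group_means = vapply(mr, mean, numeric(1)),
      short_isi_fractions = isi$shortFractions,
      behavior_means = stats::aggregate(
        cbind(gpias, ppi) ~ preset, behavior, mean))
    jsonlite::write_json(json, file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ExperimentReport <- function(x, ...) {
  cat("ExperimentReport (tinnipipe", x$version, ")\n")
  agg <- stats::aggregate(meanRate ~ preset, x$sfr, mean)
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %-14s mean SFR %.3f Hz, pooled short-ISI %.4f\n",
                agg$preset[i], agg$meanRate[i],
                x$isi$shortFractions[[agg$preset[i]]]))
  aggB <- stats::aggregate(cbind(gpias, ppi) ~ preset, x$behavior, mean)
  for (i in seq_len(nrow(aggB)))
    cat(sprintf("  %-17s GPIAS %.2f%%, PPI %.2f%%\n",
                aggB$preset[i], aggB$gpias[i], aggB$ppi[i]))
  invisible(x)
}
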