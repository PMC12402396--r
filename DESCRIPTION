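Package: tinnipipe
Title: Spontaneous Firing-Rate, Inter-Spike-Interval and Startle-Inhibition
    Analysis for Salicylate Tinnitus Electrophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of spontaneous single-unit activity recorded
    in auditory cortex together with acoustic-startle behavior, as used in
    salicylate models of tinnitus with midbrain deep brain stimulation.
    Provides zero-phase Butterworth band-pass filtering of extracellular
    voltage traces, spike detection by median-absolute-deviation
    thresholding, spike-train binarization and downsampling, boxcar
    spontaneous firing-rate series, inter-spike-interval histograms and
    short-ISI fractions, gap-prepulse (GPIAS) and prepulse (PPI) inhibition
    indices, and the accompanying statistical battery (per-timepoint
    Kruskal-Wallis with rank-biserial effect sizes and tiering,
    normality-gated group comparisons, Kolmogorov-Smirnov and chi-square ISI
    comparisons). A calibrated synthetic-data generator produces
    ground-truth recordings and startle sessions matching the four
    experimental conditions so every stage is verifiable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    nortest,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'accessors.R'
    'detect.R'
    'rate-isi.R'
    'stats.R'
    'startle.R'
    'presets.R'
    'isi-mixture.R'
    'synthesize.R'
    'preprocess.R'
    'pipeline.R'
    'experiment.R'
    'tinnipipe-package.R'
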