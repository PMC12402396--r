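---
title: "Methods: from raw voltage to group statistics in a salicylate tinnitus model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw voltage to group statistics in a salicylate tinnitus model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tinnipipe)
```

## The analysis problem

Salicylate at high doses induces reversible tinnitus-like hyperactivity in
the auditory pathway of rats. The experimental design this package serves
compares four conditions: a potential-tinnitus group and a saline control
group, each recorded in primary auditory cortex (A1) before and after
electrical stimulation of the external nucleus of the inferior colliculus.
Two families of measurements are analyzed:

* **Electrophysiology.** Single-channel extracellular voltage at 60 kHz,
  from which spontaneous firing rates (SFR) and inter-spike-interval (ISI)
  statistics are extracted over 5-minute epochs.
* **Behavior.** Acoustic-startle sessions from which gap prepulse
  inhibition (GPIAS, the tinnitus proxy) and prepulse inhibition (PPI, the
  hearing control) are computed.

The original recordings are not publicly deposited, so the package pairs
every analysis stage with a calibrated synthetic generator that encodes the
reported group-level parameters (mean rates, between-animal SDs, short-ISI
fractions, inhibition percentages). Every stage of the pipeline is thereby
testable by *parameter recovery*: generate data with known ground truth,
run the full pipeline, and check that the estimates come back unbiased.

## The signal pipeline

### Band-pass filtering

Raw traces are filtered with a zero-phase 4th-order Butterworth band-pass,
300-6000 Hz (`bandpass()`). Zero phase is realized by forward-backward
application, so the magnitude response is effectively 8th-order; we read
"4th-order" as the one-pass prototype, the common convention in
electrophysiology toolchains, and record the order in the recording
metadata. Design uses `signal::butter()`; the per-sample recursion runs in
compiled code because a 300-s trace at 60 kHz holds 18 million samples.

Edge handling matters for the first and last second of rate estimates: we
pad by odd reflection with a settling length computed from the slowest
filter pole (transients decay below 1e-12 before real samples are
reached), and trim the padding afterwards. Traces shorter than three
settling lengths are refused rather than silently corrupted.

### Spike detection

Detection (`detectSpikes()`) thresholds the filtered trace at
`-k * MAD`. Two readings of the "MAD method" exist; we implement both and
default to the *median* absolute deviation about the median
(`madEstimate()`), the robust estimator standard in spike detection. The
raw MAD of Gaussian noise is 0.6745 SD, so by default it is scaled by
1.4826 to make `k` directly interpretable in noise-SD units
(`madScaling = "normal"`). The unscaled variant remains available
(`madScaling = "raw"`). With the default `k = 5` the threshold sits at
five noise SDs: on band-limited Gaussian noise of effective bandwidth
~5.7 kHz the expected false-crossing rate is then on the order of 0.01 Hz,
negligible against the 5-15 Hz firing rates analyzed here, while a peak
SNR of 8 leaves a wide detection margin. The source study adjusted its
multiplier manually per recording; `k` is likewise a per-call parameter.

A spike is recorded at the most extreme sample within 1 ms after each
threshold crossing (negative polarity by default; extracellular spikes are
negative-dominant). Crossings within a 1-ms dead time of an accepted spike
are ignored, preventing double counts within one waveform while passing
all mixture-generated ISIs, which exceed the 1-ms refractory offset by
construction.

### Train representation and rates

Spike times are binarized at the acquisition rate and downsampled 60 kHz
to 5 kHz by OR-pooling (`downsampleTrain()`): a target bin is 1 if any of
its 12 source samples is 1. Unlike decimation this conserves event counts
for all spike pairs more than 0.2 ms apart, which the dead time
guarantees; collisions are counted and reported.

The SFR series (`sfr()`) is a centered 1-s boxcar over the 5-kHz train —
a zero-phase moving average. At the edges the count is divided by the
actual in-window coverage, avoiding the spurious rate droop a plain
convolution would produce in the first and last half second. The integral
of the series reproduces the spike count to within 0.5% (edge
quantization only), a conservation property the tests assert on every
synthetic train.

ISIs are successive differences of the detected spike times in ms
(`isis()`); histograms use half-open 5-ms bins with an explicit overflow
count (`isiHistogram()`), and the burst index is the fraction of ISIs
*strictly* below 5 ms (`shortIsiFraction()`), so a boundary interval of
exactly 5 ms is not short.

## The synthetic generator

### Spiking model

The study reports two observables per condition: the group mean rate and
the proportion of short ISIs. The generator therefore uses the simplest
renewal process in which both are analytically controllable: each ISI is a
1-ms refractory offset plus a draw from a two-component mixture,

* a **burst** component, Gamma(shape 2, mean 3 ms), producing the short
  intervals, and
* a **tonic** component, Exponential(mean `m`), producing the regular
  firing.

Given a target rate `R` (Hz) and short-ISI probability `f`,
`solveIsiMixture()` solves the two moment conditions

```
w * F_burst(4 ms) + (1 - w) * (1 - exp(-4 / m)) = f
1 + w * 3 + (1 - w) * m                         = 1000 / R
```

for the weight `w` and tonic mean `m` (the 4 ms is the 5-ms threshold
minus the refractory offset; both conditions hold to 1e-6 relative
tolerance, verified analytically and by Monte-Carlo in the tests).
Infeasible targets raise an error naming the attainable interval. Rates
are stationary within a recording: the analyzed epochs are 5-minute
spontaneous periods with no reported trend, and nonstationary profiles are
deliberately out of scope.

Per animal, the true rate is drawn from Normal(group mean, between-animal
SD) truncated at 0.5 Hz (re-drawn, so no probability mass piles up at the
bound; with the reported group parameters truncation essentially never
triggers). Seeds are derived deterministically — animal `i` of a group
with master seed `s` uses `s * 1000 + i` (noise stream offset by 500) — so
any group is a pure function of (preset, master seed), and the generators
restore the caller's RNG state.

### Voltage synthesis

Each spike contributes one template instance centered (trough) at its
spike time, in additive white Gaussian noise (`genVoltage()`). The
template (`spikeTemplate()`) is a difference of Gaussians: a sharp
negative trough (SD 0.1 ms) and a slower positive rebound (SD 0.18 ms,
45% amplitude), sampled over 1.2 ms; its effective support (above 5% of
the trough) is ~0.8 ms, shorter than the refractory offset, so even
minimum-ISI spike pairs remain resolvable. Overlaps are summed. The
default peak SNR is 8 (trough 80 uV over 10-uV noise): high enough that
the tested property is pipeline correctness rather than waveform realism,
which is explicitly not the aim. The calibration that matters — and that
the acceptance suite measures — is that detection recovers at least 99%
of ground-truth spikes with at most 1% false positives at +/-1 ms, and
that recovered rates and short-ISI fractions are unbiased.

### Condition presets

`ephysPresets()` ships the four calibrated conditions
(mean +/- between-animal SD in Hz; short-ISI fraction): tinnitus before
stimulation 15.11 +/- 2.64 (0.2489), tinnitus after 6.07 +/- 2.03
(0.2443), control before 5.17 +/- 1.31 (0.1986), control after
4.84 +/- 1.42 (0.1993); 300 s, 7 animals per group. Post-stimulation
presets carry the stimulation descriptors (100 Hz, 100 uA, 60 us) as
inert metadata — stimulation itself is represented only as a condition
label. The catalog is a versioned JSON file under `inst/extdata/`.

### Startle sessions

`genStartleSession()` builds a session of 16 gap + 16 no-gap trials
(GPIAS block) and 15 pulse + 10 prepulse + 8 no-stimulus trials (PPI
block). No-gap and pulse amplitudes are `baseline * (1 + cv * eps)` with
standard-normal `eps` and default `cv = 0.15`; gap and prepulse
amplitudes are additionally scaled by the preset's true inhibition
factors, so the ratio-of-means estimators invert the generator exactly in
the noiseless case and unbiasedly (bias < 0.5 points at `cv = 0.15`) on
average. Negative draws are clipped at zero (at `cv = 0.15` this is a
6.7-SD event). No-stimulus trials get near-zero amplitudes and enter no
index — they are summarized only as a motion baseline. Optional damped
sinusoid waveforms (40 Hz, light damping) scaled to each trial amplitude
exercise the `peakToPeak()` extraction path; the response window defaults
to 100 ms from pulse onset, a conventional value the source study does
not state.

The behavior presets encode baseline GPIAS/PPI of 44.40/92.97%
(tinnitus group) and 41.51/96.20% (controls), and post-treatment values
21.20% (tinnitus GPIAS) and 42.01/96.13% (control GPIAS/PPI). The source
report prints 42.01 +/- 9.335% both as the tinnitus post PPI and as the
control post GPIAS while describing the tinnitus PPI as unchanged from a
92.97% baseline; we read the duplicated value as a typesetting error,
keep 92.97 for the tinnitus post PPI, and flag the ambiguity in the
catalog notes.

## The statistical battery

* **Per-timepoint scan** (`timepointScan()`): at 1-s grid points
  (non-overlapping boxcar centers — adjacent 5-kHz samples share almost
  their entire window, and the original comparison grid is unstated), the
  per-animal rates of two groups are compared by the Kruskal-Wallis test.
  With two groups this is monotonically equivalent to Mann-Whitney; it is
  kept as the named test, with U exposed through the effect size. Effect
  sizes are rank-biserial correlations, `r = (wins - losses) / (nA*nB)`
  with ties counting half, tiered as low (|r| < 0.2), medium
  (0.2 <= |r| < 0.5) or high (|r| >= 0.5) only where p < 0.05. No
  multiple-testing correction is applied by default, matching the
  reporting convention of the source analysis; Benjamini-Hochberg is
  available behind `adjust = "BH"`.
* **Group means** (`compareGroupMeans()`): per-animal epoch means are
  gated through a normality test — Lilliefors-corrected
  Kolmogorov-Smirnov by default for rate summaries (the named test with
  estimated parameters requires the correction; the uncorrected variant
  would be anti-conservative), Shapiro-Wilk for behavioral indices. Both
  groups normal: t-test (paired or Welch unpaired); otherwise
  Mann-Whitney U or Wilcoxon signed-rank. The route taken is recorded in
  the result.
* **ISI distributions**: pooled per group and compared by the two-sample
  Kolmogorov-Smirnov test (`ksTwoSample()`); short-ISI proportions by
  Pearson chi-square on the 2x2 table without continuity correction
  (`chiSqShortIsi()`), with a warning when any expected count drops below
  5. Midranks are used everywhere ties can occur.
* **Totals**: per-animal total spike counts before vs after stimulation
  by paired t-test (`pairedSpikeCountTest()`), with explicit degenerate
  handling (zero-variance differences).

Degenerate inputs follow documented conventions rather than erroring
obscurely: completely tied groups return H = 0, p = 1; constant traces
are rejected as "degenerate noise estimate"; zero detections yield a
valid empty train with a warning; constant paired differences warn and
return p = 1 (no shift) or p ~ 0 (pure shift).

## Numerical and testing choices

Unit tests verify each stage against hand-computed or brute-force
oracles: rank and distance statistics are compared with exhaustive
pair-counting and ECDF-scan enumerations on all sample sizes up to 8 (to
1e-10), the filter against its analytic frequency response, the mixture
solver against 1e6-draw Monte-Carlo calibration (within 0.005 of the
target fraction), and the detection chain against ground truth at +/-1 ms.
The end-to-end recovery suite runs the study's own scale — four
conditions, 7 animals each, 300 s at 60 kHz, master seeds 42-45 — and
asserts group-mean recovery within two standard errors of the
between-animal SD, pooled short-ISI recovery within one percentage point,
behavioral recovery within three points, and a type-I error rate of the
timepoint scan within [0.03, 0.07] at the nominal 0.05 level (200 null
simulations). Unit tests use shorter recordings (2-120 s) chosen so each
assertion retains the same statistical meaning at a fraction of the cost.

Two numerical limits are asserted at what double precision supports
rather than at idealized values: filter linearity at 1e-6 relative and
time-reversal symmetry at 1e-7 relative, both bounded by round-off
amplification in the recursion at pole radius ~0.989, not by algorithmic
error.

## What the synthetic data do and do not show

The generator reproduces the *statistical targets* of the study —
stationary per-animal rates with the reported between-animal spread,
controllable burst fractions, group-level inhibition percentages with
trial-level noise. It deliberately omits: multi-unit overlap and
spike-sorting ambiguity (the analysis treats each channel as one unit
stream), stimulation artifacts, line noise and movement artifacts,
nonstationarity within an epoch, salicylate pharmacokinetics, and real
platform mechanics beyond a damped sinusoid. Passing recovery tests
therefore demonstrates that the *analysis* is unbiased and
count-conserving under the stated generative model; they cannot certify
detection performance on recordings whose noise violates these
assumptions — which is precisely why the threshold multiplier, polarity
and dead time remain per-recording parameters rather than constants.
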