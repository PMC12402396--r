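#' @include AllClasses.R
NULL

#' Construct an ephys condition preset
#'
#' @param name preset label.
#' @param groupMeanRate group mean spontaneous firing rate (Hz).
#' @param betweenAnimalSd between-animal SD of the rate (Hz).
#' @param shortIsiFraction target proportion of ISIs below 5 ms.
#' @param duration recording duration in seconds.
#' @param nAnimals animals per group.
#' @param stimulation optional named list of stimulation descriptors carried
#'   as inert metadata (e.g. pulse frequency/amplitude/width for
#'   post-stimulation conditions).
#' @return An [EphysPreset-class].
#' @export
ephysPreset <- function(name, groupMeanRate, betweenAnimalSd,
                        shortIsiFraction, duration = 300, nAnimals = 7L,
                        stimulation = list()) {
  new("EphysPreset", name = name, groupMeanRate = groupMeanRate,
      betweenAnimalSd = betweenAnimalSd, shortIsiFraction = shortIsiFraction,
      duration = duration, nAnimals = as.integer(nAnimals),
      stimulation = stimulation)
}

#' Construct a behavior condition preset
#'
#' @param name preset label.
#' @param gpiasTrue true gap inhibition in percent.
#' @param ppiTrue true prepulse inhibition in percent.
#' @param baselineAmp baseline startle amplitude (arbitrary force units).
#' @param trialCv per-trial coefficient of variation.
#' @return A [BehaviorPreset-class].
#' @export
behaviorPreset <- function(name, gpiasTrue, ppiTrue, baselineAmp = 100,
                           trialCv = 0.15) {
  new("BehaviorPreset", name = name, gpiasTrue = gpiasTrue,
      ppiTrue = ppiTrue, baselineAmp = baselineAmp, trialCv = trialCv)
}

.presetCatalog <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "preset_catalog.json",
                        package = "tinnipipe", mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' The four calibrated ephys condition presets
#'
#' Reads the shipped preset catalog: group mean firing rate, between-animal
#' SD and short-ISI fraction for the tinnitus/control groups before and
#' after midbrain stimulation. Post-phase presets carry the stimulation
#' descriptors (100 Hz, 100 uA, 60 us) as inert metadata.
#'
#' @param path optional path to an alternative catalog JSON.
#' @return Named list of [EphysPreset-class] objects
#'   (`tinnitus_pre`, `tinnitus_post`, `control_pre`, `control_post`).
#' @examples
#' ephysPresets()$control_pre
#' @export
ephysPresets <- function(path = NULL) {
  cat <- .presetCatalog(path)
  out <- lapply(names(cat$ephys), function(nm) {
    e <- cat$ephys[[nm]]
    stim <- if (is.null(e$stimulation)) list() else as.list(e$stimulation)
    ephysPreset(nm, e$group_mean_rate_hz, e$between_animal_sd_hz,
                e$short_isi_fraction, e$duration_s, e$n_animals, stim)
  })
  names(out) <- names(cat$ephys)
  out
}

#' The four calibrated behavior condition presets
#'
#' @param path optional path to an alternative catalog JSON.
#' @return Named list of [BehaviorPreset-class] objects
#'   (`tinnitus_baseline`, `control_baseline`, `tinnitus_post`,
#'   `control_post`). See the catalog notes for the handling of the
#'   ambiguously reported post-treatment PPI values.
#' @examples
#' behaviorPresets()$tinnitus_baseline
#' @export
behaviorPresets <- function(path = NULL) {
  cat <- .presetCatalog(path)
  out <- lapply(names(cat$behavior), function(nm) {
    b <- cat$behavior[[nm]]
    behaviorPreset(nm, b$gpias_percent, b$ppi_percent, b$baseline_amp,
                   b$trial_cv)
  })
  names(out) <- names(cat$behavior)
  out
}
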