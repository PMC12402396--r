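{
  "version": "1.0",
  "notes": [
    "Ephys rates are group mean +/- between-animal SD of spontaneous firing in Hz; short_isi_fraction is the group proportion of inter-spike intervals below 5 ms.",
    "Behavior values are group-mean GPIAS / PPI percentages; trial_cv is the per-trial coefficient of variation used by the session generator.",
    "The source report prints 42.01 +/- 9.335% twice: once as the tinnitus-group post-salicylate PPI (while stating PPI 'remained unchanged' from a 92.97% baseline) and once as the control-group post GPIAS. The tinnitus_post PPI here therefore keeps the unchanged baseline value 92.97; the control_post PPI uses the separately printed 96.13."
  ],
  "ephys": {
    "tinnitus_pre": {
      "group_mean_rate_hz": 15.11,
      "between_animal_sd_hz": 2.64,
      "short_isi_fraction": 0.2489,
      "duration_s": 300,
      "n_animals": 7
    },
    "tinnitus_post": {
      "group_mean_rate_hz": 6.07,
      "between_animal_sd_hz": 2.03,
      "short_isi_fraction": 0.2443,
      "duration_s": 300,
      "n_animals": 7,
      "stimulation": {
        "pulse_frequency_hz": 100,
        "pulse_amplitude_ua": 100,
        "pulse_width_us": 60
      }
    },
    "control_pre": {
      "group_mean_rate_hz": 5.17,
      "between_animal_sd_hz": 1.31,
      "short_isi_fraction": 0.1986,
      "duration_s": 300,
      "n_animals": 7
    },
    "control_post": {
      "group_mean_rate_hz": 4.84,
      "between_animal_sd_hz": 1.42,
      "short_isi_fraction": 0.1993,
      "duration_s": 300,
      "n_animals": 7,
      "stimulation": {
        "pulse_frequency_hz": 100,
        "pulse_amplitude_ua": 100,
        "pulse_width_us": 60
      }
    }
  },
  "behavior": {
    "tinnitus_baseline": {
      "gpias_percent": 44.40,
      "ppi_percent": 92.97,
      "baseline_amp": 100,
      "trial_cv": 0.15
    },
    "control_baseline": {
      "gpias_percent": 41.51,
      "ppi_percent": 96.20,
      "baseline_amp": 100,
      "trial_cv": 0.15
    },
    "tinnitus_post": {
      "gpias_percent": 21.20,
      "ppi_percent": 92.97,
      "baseline_amp": 100,
      "trial_cv": 0.15
    },
    "control_post": {
      "gpias_percent": 42.01,
      "ppi_percent": 96.13,
      "baseline_amp": 100,
      "trial_cv": 0.15
    }
  }
}
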