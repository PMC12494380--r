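# Shared study configuration for the analysis scripts.
# One synthetic cohort carries every planted structure the downstream stages
# look for: sex shifts, per-sex age slopes on splice events, an age-by-sex
# interaction block, sex-specific breakpoint trajectories, one latent batch
# factor, and a splicing-factor regulation block with known targets.

library(txaging)

results_dir <- "results"
cohort_dir <- file.path(results_dir, "cohort")

study_config <- cohort_config(
  n_donors = 240, sex_ratio = 0.5, age_range = c(20, 79),
  n_genes = 300, n_events = 300, seed = 2024,
  n_latent_factors = 1, missing_psi_rate = 0.01,
  effect_blocks = list(
    planted_effect("sex_shift", "gene", n_targets = 25, magnitude = 2),
    planted_effect("age_slope", "gene", n_targets = 25, magnitude = 0.05),
    planted_effect("interaction", "gene", n_targets = 15, magnitude = 0.05),
    planted_effect("age_slope", "event", n_targets = 20, magnitude = 0.004,
                   sex_specificity = "female_only"),
    planted_effect("age_slope", "event", n_targets = 20, magnitude = 0.004,
                   sex_specificity = "male_only"),
    planted_effect("breakpoint_trajectory", "gene", n_targets = 30,
                   magnitude = 3, breakpoint_age = 45,
                   sex_specificity = "male_only"),
    planted_effect("breakpoint_trajectory", "gene", n_targets = 30,
                   magnitude = 3, breakpoint_age = 55,
                   sex_specificity = "female_only"),
    planted_effect("sf_regulation", n_targets = 10, magnitude = 0.15)))
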