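#!/usr/bin/env Rscript
# Aging-rate curves per sex: confounder-corrected trajectories, ARIMA
# chronological filter, sliding-window MANOVA with LOESS integration,
# breakpoint detection, and the female-vs-male comparison.
source("analysis/00_config.R")

cohort <- read_cohort(cohort_dir)
pp <- preprocess_cohort(cohort)
samples <- pp$samples

svs <- estimate_surrogate_variables(pp$norm_tpm, samples)
cca <- correct_confounders_and_average(pp$norm_tpm, samples, svs)

curves <- list()
for (sx in c("F", "M")) {
  ch <- select_chronological_features(cca$trajectories[[sx]])
  cat(sprintf("%s: %d chronological genes (of %d)\n", sx,
              length(ch$selected), nrow(ch$table)))
  idx <- samples$sex == sx
  curves[[sx]] <- compute_rate_curve(cca$corrected[, idx], samples$age[idx],
                                     ch$selected)
  bp <- detect_breakpoints(curves[[sx]])$breakpoints
  cat(sprintf("  breakpoints: %s\n",
              paste(sprintf("%d (%s, rate %.2f)", bp$age, bp$type, bp$rate),
                    collapse = "; ")))
  data.table::fwrite(data.frame(age = curves[[sx]]$ages,
                                rate = curves[[sx]]$rate),
                     file.path(results_dir, sprintf("rates_%s.tsv", sx)),
                     sep = "\t")
  data.table::fwrite(bp, file.path(results_dir,
                                   sprintf("breakpoints_%s.tsv", sx)),
                     sep = "\t")
}

cmp <- compare_sex_rate_curves(curves$F, curves$M)
cat(sprintf("female vs male rates: signed-rank p = %.3g over %d shared ages\n",
            cmp$p, cmp$n_shared))
cat(sprintf("major breakpoint - female: age %s; male: age %s\n",
            cmp$major_f$age, cmp$major_m$age))
cat("the male breakpoint block is planted at 45, the female at 55;\n",
    "an earlier male breakpoint mirrors the sex-dimorphic aging signal.\n")
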