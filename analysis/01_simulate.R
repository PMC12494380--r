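#!/usr/bin/env Rscript
# Generate the synthetic study cohort and write the tab-delimited bundle.
source("analysis/00_config.R")

cohort <- generate_cohort(study_config)
print(cohort)
write_cohort(cohort, cohort_dir)

effects <- vapply(cohort$truth$effects, function(e)
  sprintf("%s (%s, n=%d, magnitude=%.3g)", e$kind, e$sex_specificity,
          length(e$target_features), e$magnitude), character(1))
cat("planted effects:\n"); cat(paste0("  - ", effects, collapse = "\n"), "\n")
cat("bundle written to", cohort_dir, "\n")
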