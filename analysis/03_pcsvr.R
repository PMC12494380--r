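#!/usr/bin/env Rscript
# Quantify how much of the transcriptome variation sex and age explain:
# pcSVR per contrast and data type, with subsampling permutation p-values,
# with and without sex-chromosome features.
source("analysis/00_config.R")

cohort <- read_cohort(cohort_dir)

screens <- list()
for (contrast in c("sex", "age")) {
  for (excl in c(FALSE, TRUE)) {
    scr <- pcsvr_screen(cohort, contrast, exclude_sex_chromosomes = excl,
                        n_iter = 1000, seed = 7)
    scr$sex_chromosomes_excluded <- excl
    screens[[length(screens) + 1]] <- scr
  }
}
tab <- do.call(rbind, screens)
data.table::fwrite(tab, file.path(results_dir, "pcsvr_results.tsv"), sep = "\t")

cat("pcSVR screen (empirical p, cutoff 0.1):\n")
print(tab[, c("tissue", "data_type", "contrast", "sex_chromosomes_excluded",
              "pcsvr", "p", "significant")], row.names = FALSE)
cat("\nA planted sex shift on autosomal genes keeps the sex contrast\n",
    "significant after sex-chromosome exclusion; the age contrast reflects\n",
    "the planted age and breakpoint blocks.\n")
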