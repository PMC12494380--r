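# shared fixture builders; all cohorts are generated in code at test time

make_plain_cohort <- function(n_donors = 60, n_genes = 80, n_events = 60,
                              seed = 1, ...) {
  generate_cohort(cohort_config(n_donors = n_donors, n_genes = n_genes,
                                n_events = n_events, seed = seed, ...))
}

# two-group Gaussian matrix with a planted mean shift on a feature subset
make_shift_matrix <- function(n_per_group = 100, n_features = 500,
                              shift = 1.5, frac_affected = 0.3, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  M <- matrix(rnorm(n * n_features), n, n_features)
  affected <- seq_len(round(frac_affected * n_features))
  M[(n_per_group + 1):n, affected] <- M[(n_per_group + 1):n, affected] + shift
  list(values = t(M),   # features x samples
       groups = rep(c("A", "B"), each = n_per_group), affected = affected)
}
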