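test_that("interaction model recovers noiseless coefficients exactly", {
  samples <- data.frame(sex = rep(c("F", "M"), each = 20),
                        age = rep(25:44, 2))
  y <- 1 + 2 * (samples$sex == "M") + 0.1 * samples$age
  fit <- fit_interaction_model(rbind(f1 = y), samples)
  expect_equal(unname(fit$coefficients["f1", c("intercept", "sex", "age")]),
               c(1, 2, 0.1), tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["f1", "sex_age"]), 0, tolerance = 1e-8)
  # with an interaction planted, gamma is recovered too
  y2 <- y + 0.05 * samples$age * (samples$sex == "M")
  fit2 <- fit_interaction_model(rbind(f1 = y2), samples)
  expect_equal(unname(fit2$coefficients["f1", "sex_age"]), 0.05,
               tolerance = 1e-8)
})

test_that("interaction-coefficient type-I error is nominal under the null", {
  set.seed(20)
  n <- 200
  samples <- data.frame(sex = rep(c("F", "M"), each = n / 2),
                        age = sample(20:79, n, replace = TRUE))
  Y <- matrix(rnorm(1000 * n), 1000, n,
              dimnames = list(sprintf("f%04d", 1:1000), NULL))
  fit <- fit_interaction_model(Y, samples)
  frac <- mean(fit$p[, "sex_age"] < 0.05)
  band <- 1.96 * sqrt(0.05 * 0.95 / 1000)
  expect_gt(frac, 0.05 - band)
  expect_lt(frac, 0.05 + band)
})

test_that("surrogate variables capture a planted batch factor", {
  co <- make_plain_cohort(n_donors = 120, n_genes = 300, n_events = 20,
                          seed = 5, n_latent_factors = 1,
                          missing_psi_rate = 0)
  nv <- normalize_scaling(log2(co$tpm + 1))
  svs <- estimate_surrogate_variables(nv, co$samples)
  expect_gte(svs$k, 1)
  expect_gt(abs(cor(svs$sv[, 1], co$truth$latent_factors[, 1])), 0.9)
  # diagnostics report the association with a known covariate
  covs <- data.frame(batch = co$truth$latent_factors[, 1] > 0)
  svs2 <- estimate_surrogate_variables(nv, co$samples, k = 1,
                                       covariates = covs)
  expect_true(any(svs2$diagnostics$p < 0.01))
  # k = 0 yields an empty SV set
  sv0 <- estimate_surrogate_variables(nv, co$samples, k = 0)
  expect_equal(sv0$k, 0)
  expect_equal(ncol(sv0$sv), 0)
})

test_that("differential calls require both the p-value and the effect gate", {
  samples <- data.frame(sex = rep(c("F", "M"), 30),
                        age = rep(c(25, 70), each = 30))
  young <- samples$age < 40
  # expression: strong p, weak fold change vs strong both
  tpm <- rbind(weak_fc = ifelse(young, 10, 13),       # FC 1.3
               strong = ifelse(young, 10, 40))        # FC 4
  tpm <- tpm + matrix(abs(rnorm(2 * 60, 0, 0.1)), 2)
  nv <- normalize_scaling(tpm)
  fit <- fit_interaction_model(nv, samples)
  calls <- call_differential(fit, tpm, samples, "expression", "age")
  expect_false(calls$called[calls$feature == "weak_fc"])
  expect_true(calls$called[calls$feature == "strong"])
  # splicing: delta-PSI gate at 0.05
  psi <- rbind(small = ifelse(young, 0.50, 0.54) + rnorm(60, 0, 0.002),
               big = ifelse(young, 0.50, 0.57) + rnorm(60, 0, 0.002))
  nvp <- normalize_scaling(psi)
  fitp <- fit_interaction_model(nvp, samples)
  cp <- call_differential(fitp, psi, samples, "splicing", "age")
  expect_false(cp$called[cp$feature == "small"])
  expect_true(cp$called[cp$feature == "big"])
  expect_equal(cp$effect[cp$feature == "big"], 0.07, tolerance = 0.01)
})

test_that("permutation FDR is near zero for strong effects, calibrated for null", {
  set.seed(21)
  n <- 80
  samples <- data.frame(sex = rep(c("F", "M"), n / 2),
                        age = sample(c(21:39, 61:79), n, replace = TRUE))
  old <- samples$age > 60
  tpm <- rbind(strong = ifelse(old, 40, 10) + abs(rnorm(n, 0, 0.5)))
  null_m <- matrix(10 + abs(rnorm(20 * n, 0, 2)), 20, n,
                   dimnames = list(sprintf("n%02d", 1:20), NULL))
  tpm <- rbind(tpm, null_m)
  nv <- normalize_scaling(tpm)
  pf <- permutation_fdr(nv, tpm, samples, data_type = "expression",
                        coefficient = "age", n_perm = 100, seed = 3)
  expect_equal(unname(pf$fdr["strong"]), 0, tolerance = 0.02)
  expect_true(pf$original$called[pf$original$feature == "strong"])
  expect_length(pf$overlap_fraction, 100)
})

test_that("sex-stratified fits label sex-biased features correctly", {
  samples <- data.frame(sex = rep(c("F", "M"), each = 40),
                        age = rep(seq(20, 78, length.out = 40), 2))
  fem <- samples$sex == "F"
  y_f <- ifelse(fem, 0.5 * samples$age, 0)          # female slope only
  y_b <- 0.4 * samples$age                           # both sexes
  raw <- rbind(f_only = y_f + 10, both = y_b + 10)
  strat <- fit_sex_stratified_model(raw, raw, samples, data_type = "expression")
  lab <- strat$labels
  expect_equal(unname(lab$beta_F[lab$feature == "f_only"]), 0.5,
               tolerance = 1e-8)
  expect_equal(unname(lab$beta_M[lab$feature == "f_only"]), 0,
               tolerance = 1e-8)
  expect_equal(lab$label[lab$feature == "f_only"], "female_specific")
  expect_equal(lab$label[lab$feature == "both"], "common")
  # labels partition: a feature is never in two classes
  expect_false(any(duplicated(lab$feature)))
})

test_that("hypergeometric overlap matches exact enumeration", {
  u <- paste0("g", 1:10)
  p <- overlap_significance(u[1:4], u[1:5], u)
  expect_equal(p, 6 / 252, tolerance = 1e-12)
  expect_equal(overlap_significance(u[1:3], u[5:7], u), 1)
  expect_equal(overlap_significance(u, u, u), 1)
  expect_error(overlap_significance("a", "b", character(0)), "universe")
  # brute-force oracle on small universes: enumerate all B-sets
  set.seed(22)
  for (rep in 1:5) {
    U <- paste0("x", 1:8)
    A <- sample(U, 4)
    B <- sample(U, 3)
    k <- length(intersect(A, B))
    combos <- combn(8, 3)
    tail_p <- mean(apply(combos, 2, function(ix)
      length(intersect(U[ix], A)) >= k))
    expect_equal(overlap_significance(A, B, U), tail_p, tolerance = 1e-12)
  }
})

test_that("effect-size correlation and Fisher z behave as oracles predict", {
  lab <- data.frame(beta_F = 1:20, beta_M = 1:20)
  ec <- effect_size_correlation(lab)
  expect_equal(ec$rho, 1)
  set.seed(23)
  lab2 <- data.frame(beta_F = rnorm(500), beta_M = rnorm(500))
  expect_lt(abs(effect_size_correlation(lab2)$rho), 0.15)
  cz <- compare_correlations(0.5, 100, 0.2, 100)
  expect_equal(cz$z, 2.4136, tolerance = 1e-4)
  expect_equal(cz$p, 0.0158, tolerance = 1e-3)
  expect_equal(compare_correlations(0.4, 50, 0.4, 50)$z, 0)
  sw <- compare_correlations(0.2, 100, 0.5, 100)
  expect_equal(sw$z, -cz$z)
  expect_equal(sw$p, cz$p)
  expect_error(compare_correlations(1, 10, 0.5, 10), "< 1")
})

test_that("sample-size bias regression recovers noiseless slopes", {
  size <- c(100, 200, 300, 400, 500)
  n_diff <- 10 + 0.5 * size
  expect_message(bf <- sample_size_bias_model(n_diff, size,
                                              detected = rep(1000, 5)),
                 "Detected")
  expect_equal(unname(bf$coefficients["Size"]), 0.5, tolerance = 1e-10)
  expect_error(sample_size_bias_model(n_diff[1:3], size[1:3], rep(1, 3)),
               "4 tissues")
})
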