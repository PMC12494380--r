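test_that("pcSVR reproduces the one-dimensional hand value", {
  emb <- list(scores = matrix(c(0, 2, 4, 6), 4, 1),
              groups = factor(c("x", "x", "y", "y")), n_pcs = 1)
  res <- compute_pcsvr(emb)
  expect_equal(res$pcsvr, 4 / sqrt(2), tolerance = 1e-12)
  expect_equal(res$s2x, 2)
  expect_equal(res$s2y, 2)
  # identical point sets give zero; coincident constant groups error
  emb0 <- list(scores = matrix(c(1, 2, 1, 2), 4, 1),
               groups = factor(c("x", "x", "y", "y")), n_pcs = 1)
  expect_equal(compute_pcsvr(emb0)$pcsvr, 0)
  embc <- list(scores = matrix(1, 4, 1),
               groups = factor(c("x", "x", "y", "y")), n_pcs = 1)
  expect_error(compute_pcsvr(embc), "dispersion")
})

test_that("pcSVR is symmetric in groups and rotation invariant", {
  set.seed(5)
  sc <- matrix(rnorm(40 * 3), 40, 3)
  g <- factor(rep(c("x", "y"), each = 20))
  emb <- list(scores = sc, groups = g, n_pcs = 3)
  emb_sw <- list(scores = sc, groups = factor(g, levels = c("y", "x")),
                 n_pcs = 3)
  expect_equal(compute_pcsvr(emb)$pcsvr, compute_pcsvr(emb_sw)$pcsvr)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))          # random orthogonal rotation
  emb_rot <- list(scores = sc %*% Q, groups = g, n_pcs = 3)
  expect_equal(compute_pcsvr(emb)$pcsvr, compute_pcsvr(emb_rot)$pcsvr,
               tolerance = 1e-10)
})

test_that("PC selection follows the cumulative-variance rule", {
  # rank-1 data: one PC suffices at any cutoff
  set.seed(6)
  vals <- outer(rnorm(30), rnorm(20))          # features x samples, rank 1
  g <- rep(c("a", "b"), each = 10)
  expect_equal(fit_pca_embedding(vals, g, 0.8)$n_pcs, 1)
  # isotropic 10-D: 80% of variance needs at least 8 of 10 directions
  iso <- t(matrix(rnorm(4000 * 10), ncol = 10))
  gi <- rep(c("a", "b"), each = 2000)
  expect_gte(fit_pca_embedding(iso, gi, 0.8)$n_pcs, 8)
  # selected-PC count is non-decreasing in the cutoff
  set.seed(7)
  vals2 <- matrix(rnorm(50 * 40), 50, 40)
  g2 <- rep(c("a", "b"), each = 20)
  k1 <- fit_pca_embedding(vals2, g2, 0.5)$n_pcs
  k2 <- fit_pca_embedding(vals2, g2, 0.9)$n_pcs
  expect_lte(k1, k2)
  expect_error(fit_pca_embedding(vals2, c("a", rep("b", 39)), 0.8), "2 samples")
})

test_that("with one PC the statistic reduces to the classical SNR", {
  set.seed(8)
  vals <- outer(rnorm(25), c(rnorm(15), rnorm(15, 2)))
  g <- rep(c("a", "b"), each = 15)
  emb <- fit_pca_embedding(vals, g, 0.8)
  expect_equal(emb$n_pcs, 1)
  s <- emb$scores[, 1]
  snr <- abs(mean(s[1:15]) - mean(s[16:30])) /
    sqrt(var(s[1:15]) / 15 + var(s[16:30]) / 15)
  expect_equal(compute_pcsvr(emb)$pcsvr, snr, tolerance = 1e-10)
})

test_that("planted group separation drives pcSVR above 1, monotonically", {
  means <- sapply(c(0, 0.5, 1.5), function(shift) {
    sm <- make_shift_matrix(n_per_group = 60, n_features = 200, shift = shift,
                            seed = 42)
    compute_pcsvr(fit_pca_embedding(sm$values, sm$groups, 0.8))$pcsvr
  })
  expect_true(all(diff(means) > 0))
  expect_gt(means[3], 1)
})

test_that("empirical p-value machinery is well-formed and null-valid", {
  sm <- make_shift_matrix(n_per_group = 10, n_features = 30, shift = 2,
                          seed = 9)
  res <- pcsvr_test(sm$values, sm$groups, n_iter = 200, seed = 1)
  expect_length(res$null_values, 200)
  expect_gte(res$empirical_p, 0)
  expect_lte(res$empirical_p, 1)
  expect_equal(res$resolution, 1 / 200)
  expect_lt(res$empirical_p, 0.1)      # strong planted shift is detected
  boot <- pcsvr_test(sm$values, sm$groups, scheme = "bootstrap",
                     n_iter = 200, seed = 1)
  expect_lt(boot$empirical_p, 0.1)
  # under exchangeable groups the test never rejects above its nominal rate:
  # the observed statistic is a subsample average, so the procedure is valid
  # but conservative at any cutoff
  set.seed(10)
  ps <- replicate(40, {
    M <- matrix(rnorm(16 * 30), 30, 16)
    colnames(M) <- paste0("s", 1:16)
    pcsvr_test(M, rep(c("a", "b"), each = 8), n_iter = 100,
               seed = sample.int(1e6, 1))$empirical_p
  })
  expect_lte(mean(ps < 0.1), 0.2)
  expect_error(pcsvr_test(sm$values[, c(1:3, 11:13)],
                          sm$groups[c(1:3, 11:13)]), "4 samples")
})

test_that("the screen attributes sex effects to sex-chromosome features", {
  cfg0 <- cohort_config(n_donors = 80, n_genes = 100, n_events = 30,
                        seed = 17, missing_psi_rate = 0)
  co0 <- generate_cohort(cfg0)
  xy <- co0$features$feature_id[co0$features$kind == "gene" &
                                  co0$features$chromosome %in% c("chrX", "chrY")]
  expect_gt(length(xy), 2)
  cfg <- cohort_config(n_donors = 80, n_genes = 100, n_events = 30, seed = 17,
                       missing_psi_rate = 0,
                       effect_blocks = list(planted_effect(
                         "sex_shift", "gene", target_features = xy,
                         magnitude = 6)))
  co <- generate_cohort(cfg)
  scr_in <- pcsvr_screen(co, "sex", exclude_sex_chromosomes = FALSE,
                         n_iter = 200, seed = 2)
  scr_ex <- pcsvr_screen(co, "sex", exclude_sex_chromosomes = TRUE,
                         n_iter = 200, seed = 2)
  ge_in <- scr_in[scr_in$data_type == "GE", ]
  ge_ex <- scr_ex[scr_ex$data_type == "GE", ]
  expect_true(ge_in$significant)
  expect_false(ge_ex$significant)
})

test_that("sex-specific age effects and empty age groups are handled", {
  cfg <- cohort_config(n_donors = 120, n_genes = 80, n_events = 30, seed = 19,
                       missing_psi_rate = 0,
                       effect_blocks = list(planted_effect(
                         "age_slope", "gene", n_targets = 30, magnitude = 0.15,
                         sex_specificity = "male_only")))
  co <- generate_cohort(cfg)
  scr_m <- pcsvr_screen(co, "age", sex_stratum = "M", n_iter = 100, seed = 3)
  scr_f <- pcsvr_screen(co, "age", sex_stratum = "F", n_iter = 100, seed = 3)
  expect_gt(scr_m$pcsvr[scr_m$data_type == "GE"],
            scr_f$pcsvr[scr_f$data_type == "GE"])
  # all donors in the excluded middle band: every stratum skipped
  co$samples$age <- sample(45:55, nrow(co$samples), replace = TRUE)
  scr_mid <- pcsvr_screen(co, "age", n_iter = 50, seed = 4)
  expect_true(all(scr_mid$skipped))
})
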