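test_that("SF-event correlation passes monotone pairs and skips degenerate ones", {
  set.seed(30)
  x <- seq(1, 5, length.out = 20)
  sf <- rbind(SF1 = x, SF_const = rep(2, 20))
  psi <- rbind(e1 = plogis(x),                  # strictly increasing in SF1
               e2 = runif(20))
  ct <- correlate_sf_events(sf, psi)
  r11 <- ct[ct$sf == "SF1" & ct$event == "e1", ]
  expect_equal(r11$rho, 1)
  expect_true(r11$pass)
  expect_true(all(ct$skipped[ct$sf == "SF_const"]))
  small <- correlate_sf_events(sf[, 1:4], psi[, 1:4])
  expect_true(all(small$skipped))
  # null calibration: ~5% of independent pairs pass
  set.seed(31)
  sf_n <- matrix(rnorm(25 * 40), 25, 40, dimnames = list(paste0("s", 1:25), NULL))
  ps_n <- matrix(runif(40 * 40), 40, 40, dimnames = list(paste0("e", 1:40), NULL))
  ctn <- correlate_sf_events(sf_n, ps_n)
  expect_lt(mean(ctn$pass), 0.10)
  expect_gt(mean(ctn$pass), 0.01)
})

test_that("knockdown regression estimates the planted shift with a t oracle", {
  ev <- paste0("e", 1:10)
  kd <- generate_knockdown_experiment(ev, list(SF1 = ev[1:3]), n_reps = 4,
                                      effect = 0.3, noise_sd = 0.01, seed = 7)
  fitk <- knockdown_differential(kd)
  tgt <- fitk[fitk$event %in% ev[1:3], ]
  expect_true(all(abs(tgt$beta_g - 0.3) < 0.02))
  expect_true(all(tgt$p < 0.01))
  # oracle: identical to a two-sample equal-variance t-test
  one <- kd[kd$event == "e1", ]
  tt <- t.test(psi ~ arm, one, var.equal = TRUE)
  expect_equal(fitk$p[fitk$event == "e1"], tt$p.value, tolerance = 1e-10)
  # identical arms: beta ~ 0, p large
  kd0 <- generate_knockdown_experiment(ev, list(SF1 = character(0)),
                                       n_reps = 4, effect = 0.5, seed = 8)
  f0 <- knockdown_differential(kd0)
  expect_lt(mean(f0$pass), 0.3)
  expect_error(knockdown_differential(kd[kd$arm == "control", ]), "replicates")
})

test_that("motif bin test matches exact rank-sum enumeration on small bins", {
  # two bins of 5 scores, no ties: enumerate all 252 group assignments
  lo <- c(0.11, 0.13, 0.17, 0.19, 0.23)
  hi <- c(1.31, 1.37, 1.41, 1.43, 1.47)
  ev <- motif_binding_evidence(c(hi, lo), bin_width = 5)
  pooled <- c(hi, lo)
  obs <- sum(rank(pooled)[1:5])
  combos <- combn(10, 5)
  null_stats <- apply(combos, 2, function(ix) sum(rank(pooled)[ix]))
  exact_p <- mean(abs(null_stats - mean(null_stats)) >=
                    abs(obs - mean(null_stats)))
  expect_equal(ev$p, exact_p, tolerance = 1e-10)
  expect_true(ev$pass)
  # failures on each criterion
  expect_false(motif_binding_evidence(rep(c(0.5, 0.49), 50))$pass)  # max <= 1
  elevated_low_max <- c(rep(0.1, 20), seq(0.7, 0.8, length.out = 20),
                        rep(0.1, 20))
  ev2 <- motif_binding_evidence(elevated_low_max)
  expect_lt(ev2$p, 0.05)
  expect_false(ev2$pass)                                            # max 0.8
  expect_error(motif_binding_evidence(rep(1, 25)), "two bins")
})

test_that("network edges are exactly the conjunction of the three evidences", {
  sfs <- c("sf1", "sf2"); evs <- c("e1", "e2")
  corr <- expand.grid(sf = sfs, event = evs, stringsAsFactors = FALSE)
  corr$rho <- 0.9; corr$p <- 0.001; corr$pass <- c(TRUE, TRUE, TRUE, FALSE)
  kd <- corr[, 1:2]; kd$beta_g <- 0.3; kd$p <- 0.001
  kd$pass <- c(TRUE, TRUE, FALSE, TRUE)
  motif <- corr[, 1:2]; motif$max_score <- 2; motif$p_motif <- 0.001
  motif$motif_pass <- c(TRUE, FALSE, TRUE, TRUE)
  net <- build_network(corr, kd, motif, sfs, evs, sex = "M")
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$sf, "sf1")
  expect_equal(net$edges$event, "e1")
  expect_equal(net$edges$sex, "M")
  # brute-force set algebra oracle
  key <- function(d, f) paste(d$sf, d$event)[f]
  manual <- intersect(intersect(key(corr, corr$pass), key(kd, kd$pass)),
                      key(motif, motif$motif_pass))
  expect_setequal(paste(net$edges$sf, net$edges$event), manual)
  # id mismatch errors; empty event set yields a valid empty network
  expect_error(build_network(corr[-1, ], kd, motif, sfs, evs), "absent")
  empty <- build_network(corr, kd, motif, sfs, character(0))
  expect_equal(nrow(empty$edges), 0)
})

test_that("a planted regulator is recovered among decoys end to end", {
  set.seed(33)
  recovered <- 0
  decoy_total <- 0
  for (s in 1:5) {
    cfg <- cohort_config(n_donors = 120, sex_ratio = 1, n_genes = 40,
                         n_events = 40, seed = 400 + s, missing_psi_rate = 0,
                         effect_blocks = list(planted_effect(
                           "sf_regulation", n_targets = 6, magnitude = 0.15)))
    co <- generate_cohort(cfg)
    ef <- co$truth$effects[[1]]
    decoys <- setdiff(rownames(co$tpm), ef$sf)[1:10]
    sfs <- c(ef$sf, decoys)
    evs <- ef$target_features
    corr <- correlate_sf_events(co$tpm[sfs, ], co$psi[evs, ])
    kd <- generate_knockdown_experiment(
      evs, setNames(c(list(evs), rep(list(character(0)), 10)), sfs),
      n_reps = 4, effect = 0.3, seed = 500 + s)
    prof <- generate_motif_profiles(evs, sfs,
                                    data.frame(sf = ef$sf, event = evs),
                                    seed = 600 + s)
    net <- build_network(corr, knockdown_differential(kd), prof, sfs, evs)
    sm <- net$summary
    recovered <- recovered + (sm$n_edges[sm$sf == ef$sf] > 0)
    decoy_total <- decoy_total + sum(sm$n_edges[sm$sf != ef$sf])
  }
  expect_gte(recovered, 4)
  expect_lte(decoy_total, 2)
})
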