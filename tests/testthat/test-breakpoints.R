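test_that("confounder correction averages by sex and age and removes batch", {
  samples <- data.frame(sex = c("F", "F", "M"), age = c(30, 30, 41))
  vals <- rbind(f1 = c(4, 6, 5))
  cca <- correct_confounders_and_average(vals, samples, NULL)
  expect_equal(unname(cca$trajectories$F["f1", "30"]), 5)   # (4+6)/2
  expect_equal(unname(cca$trajectories$M["f1", "41"]), 5)
  expect_equal(cca$corrected, vals)                          # zero SVs: identity
  # a planted batch factor is removed, recovering the age trend
  set.seed(40)
  n <- 120
  s2 <- data.frame(sex = rep("M", n), age = rep(20:79, 2))
  batch <- rnorm(n)
  truth <- 0.05 * s2$age
  Y <- rbind(g = truth + 2 * batch + rnorm(n, 0, 0.1))
  cca2 <- correct_confounders_and_average(Y, s2, matrix(batch, ncol = 1))
  rmse_corr <- sqrt(mean((cca2$corrected["g", ] - mean(Y["g", ]) -
                            (truth - mean(truth)))^2))
  rmse_raw <- sqrt(mean((Y["g", ] - mean(Y["g", ]) - (truth - mean(truth)))^2))
  expect_lt(rmse_corr, rmse_raw / 2)
})

test_that("ARIMA filter keeps trending series and drops white noise", {
  set.seed(41)
  n_ages <- 50
  traj <- rbind(noise = rnorm(n_ages),
                walk = cumsum(arima.sim(list(ar = 0.7), n = n_ages)),
                ramp = 0.08 * seq_len(n_ages) + rnorm(n_ages, 0, 0.5),
                const = rep(1, n_ages))
  colnames(traj) <- 20 + seq_len(n_ages) - 1
  ch <- select_chronological_features(traj)
  expect_false("noise" %in% ch$selected)
  expect_true("walk" %in% ch$selected)
  expect_true("ramp" %in% ch$selected)
  expect_false("const" %in% ch$selected)       # constant excluded, no error
  expect_true(all(ch$table$d[ch$table$keep] >= 1))
  expect_true(all(ch$table$coef_sum[ch$table$keep] > 0))
  # decision is deterministic for a fixed trajectory
  ch2 <- select_chronological_features(traj)
  expect_identical(ch$table, ch2$table)
  expect_error(select_chronological_features(traj[, 1:10]), "20 age points")
})

test_that("the false-inclusion rate of the ARIMA filter on noise is low", {
  set.seed(42)
  traj <- matrix(rnorm(60 * 40), 60, 40,
                 dimnames = list(sprintf("n%02d", 1:60), 20:59))
  ch <- select_chronological_features(traj)
  expect_lte(length(ch$selected) / 60, 0.10)
})

test_that("closed-form two-group MANOVA agrees with the stats::manova oracle", {
  set.seed(43)
  for (rep in 1:5) {
    A <- matrix(rnorm(12 * 3), 12, 3)
    B <- matrix(rnorm(10 * 3, sample(0:1, 1)), 10, 3)
    mine <- txaging:::.two_group_manova_p(A, B)
    g <- factor(rep(c("a", "b"), c(12, 10)))
    or <- summary(manova(rbind(A, B) ~ g), test = "Pillai")$stats[1, "Pr(>F)"]
    expect_equal(mine, unname(or), tolerance = 1e-10)
  }
})

test_that("rate curve is invariant to feature order and finds planted shifts", {
  set.seed(44)
  n <- 160
  ages <- rep(20:79, length.out = n)
  shift <- 1.5 * plogis(ages - 50)
  Y <- rbind(matrix(rep(shift, 12), 12, byrow = TRUE) +
               matrix(rnorm(12 * n, 0, 0.8), 12),
             matrix(rnorm(8 * n), 8, n))
  rownames(Y) <- sprintf("f%02d", 1:20)
  rc <- compute_rate_curve(Y, ages, rownames(Y), w_range = 5:10)
  perm <- sample(rownames(Y))
  rc_perm <- compute_rate_curve(Y[perm, ], ages, rownames(Y), w_range = 5:10)
  expect_equal(rc$rate, rc_perm$rate, tolerance = 1e-8)
  peak <- rc$ages[which.max(rc$rate)]
  expect_lte(abs(peak - 50), 5)
  expect_error(compute_rate_curve(Y, ages, rownames(Y)[1:2]), "at least 3")
})

test_that("breakpoint detection applies the 10% prominence rule", {
  bp <- detect_breakpoints(list(ages = 25:31, rate = c(1, 2, 5, 2, 1, 3, 1)))
  expect_equal(bp$breakpoints$age, c(27, 30))
  expect_equal(bp$breakpoints$type, c("global_max", "local_max"))
  uni <- detect_breakpoints(list(ages = 40:44, rate = c(1, 2, 3, 2, 1)))
  expect_equal(uni$breakpoints$age, 42)
  # secondary peak at 8% prominence is rejected
  low <- detect_breakpoints(list(ages = 25:31,
                                 rate = c(1, 2, 5, 2, 1, 1.4, 1)))
  expect_equal(low$breakpoints$age, 27)
  expect_warning(flat <- detect_breakpoints(list(ages = 1:6, rate = rep(2, 6))),
                 "flat")
  expect_equal(nrow(flat$breakpoints), 0)
  expect_error(detect_breakpoints(list(ages = 1:3, rate = 1:3)), "5 points")
})

test_that("breakpoint detector matches a brute-force extremum scan", {
  brute <- function(ages, rate) {
    n <- length(rate)
    maxima <- Filter(function(i) rate[i] > rate[i - 1] && rate[i] >= rate[i + 1],
                     2:(n - 1))
    if (!length(maxima)) return(numeric(0))
    minima <- c(1, Filter(function(i) rate[i] <= rate[i - 1] &&
                            rate[i] <= rate[i + 1], 2:(n - 1)), n)
    g <- maxima[which.max(rate[unlist(maxima)])]
    keep <- g
    for (m in setdiff(unlist(maxima), g)) {
      nm <- minima[[which.min(abs(ages[unlist(minima)] - ages[m]))]]
      if ((rate[m] - rate[nm]) / rate[g] > 0.10) keep <- c(keep, m)
    }
    sort(ages[keep])
  }
  set.seed(45)
  for (rep in 1:20) {
    rate <- abs(cumsum(rnorm(30)))
    ages <- seq(20, by = 2, length.out = 30)
    got <- suppressWarnings(detect_breakpoints(list(ages = ages, rate = rate)))
    expect_equal(got$breakpoints$age, brute(ages, rate))
  }
})

test_that("sex comparison uses the exact signed-rank null and major breakpoints", {
  ages <- 30:49
  base <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 9, 8, 7, 6, 5, 4, 3, 2, 1, 0.5)
  cf <- list(ages = ages, rate = base)
  cm <- list(ages = ages, rate = base + 0.5)
  cmp <- compare_sex_rate_curves(cf, cm)
  expect_equal(cmp$p, 2^-19, tolerance = 1e-12)
  expect_equal(cmp$major_f$age, cmp$major_m$age)
  ident <- compare_sex_rate_curves(cf, cf)
  expect_true(is.na(ident$p))
  expect_match(ident$note, "identical")
  short <- compare_sex_rate_curves(list(ages = 1:3, rate = 1:3),
                                   list(ages = 10:12, rate = 1:3))
  expect_true(is.na(short$p))
})

test_that("a planted breakpoint is recovered within tolerance on a cohort", {
  cfg <- cohort_config(n_donors = 240, n_genes = 120, n_events = 20, seed = 11,
                       missing_psi_rate = 0,
                       effect_blocks = list(planted_effect(
                         "breakpoint_trajectory", "gene", n_targets = 48,
                         magnitude = 3, breakpoint_age = 50)))
  co <- generate_cohort(cfg)
  nv <- normalize_scaling(log2(co$tpm + 1))
  cca <- correct_confounders_and_average(nv, co$samples, NULL)
  ch <- select_chronological_features(cca$trajectories$M)
  expect_gte(sum(co$truth$effects[[1]]$target_features %in% ch$selected), 40)
  idx <- co$samples$sex == "M"
  rc <- compute_rate_curve(cca$corrected[, idx], co$samples$age[idx],
                           ch$selected, w_range = 5:10)
  bp <- detect_breakpoints(rc)
  major <- bp$breakpoints$age[bp$breakpoints$type == "global_max"]
  expect_lte(abs(major - 50), 3)
})
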