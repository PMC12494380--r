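#' Estimate surrogate variables for unmodeled confounding
#'
#' Wraps surrogate variable analysis (two-pass residual decomposition): the
#' primary design (sex + age + age-by-sex) is regressed out, leading factors of
#' the residual matrix are extracted, and the number of factors is chosen by a
#' permutation-based eigenvalue test when `k` is not supplied. SV columns are
#' scaled to unit variance. Diagnostic correlations between each SV and known
#' covariates (point-biserial for binary, Spearman otherwise) are returned so
#' confounder capture can be audited.
#'
#' @param values features x samples matrix (or `tx_norm`).
#' @param samples data.frame with `sex` ("F"/"M") and `age` columns.
#' @param k number of SVs; `NULL` selects it by the permutation eigenvalue test.
#' @param covariates optional data.frame of known covariates for diagnostics.
#' @return list of class `tx_svset`: `sv` (samples x k), `k`, `method`,
#'   `diagnostics`.
#' @export
estimate_surrogate_variables <- function(values, samples, k = NULL,
                                         covariates = NULL) {
  values <- .as_values(values)
  sex <- .sex01(samples$sex)
  age <- samples$age
  mod <- stats::model.matrix(~ sex * age)
  .assert(qr(mod)$rank == ncol(mod), "primary design matrix is rank deficient")
  mod0 <- stats::model.matrix(~ 1, data = data.frame(x = seq_len(ncol(values))))
  if (is.null(k))
    k <- sva::num.sv(values, mod, method = "be")
  .assert(k <= ncol(values) - ncol(mod),
          "k exceeds the residual rank of the design")
  if (k == 0) {
    svm <- matrix(numeric(0), nrow = ncol(values), ncol = 0)
  } else {
    fit <- suppressMessages(utils::capture.output(
      svobj <- sva::sva(values, mod, mod0, n.sv = k)))
    svm <- as.matrix(svobj$sv)
    svm <- scale(svm, center = TRUE, scale = TRUE)  # unit-variance columns
    colnames(svm) <- sprintf("SV%d", seq_len(ncol(svm)))
  }
  diag_tab <- NULL
  if (!is.null(covariates) && ncol(svm) > 0) {
    diag_tab <- do.call(rbind, lapply(names(covariates), function(cv) {
      x <- covariates[[cv]]
      binary <- length(unique(x)) == 2
      xn <- if (is.numeric(x)) x else as.numeric(as.factor(x))
      do.call(rbind, lapply(seq_len(ncol(svm)), function(j) {
        ct <- if (binary)
          stats::cor.test(svm[, j], xn)  # point-biserial = Pearson w/ binary
        else
          suppressWarnings(stats::cor.test(svm[, j], xn, method = "spearman"))
        data.frame(covariate = cv, sv = colnames(svm)[j],
                   method = if (binary) "point-biserial" else "spearman",
                   estimate = unname(ct$estimate), p = ct$p.value,
                   stringsAsFactors = FALSE)
      }))
    }))
  }
  structure(list(sv = svm, k = ncol(svm), method = "sva (be)",
                 diagnostics = diag_tab),
            class = "tx_svset")
}

# Build the interaction design matrix, dropping SVs collinear with the design.
.design_interaction <- function(samples, svs) {
  sex <- .sex01(samples$sex)
  age <- samples$age
  X <- cbind(intercept = 1, sex = sex, age = age, sex_age = sex * age)
  if (!is.null(svs)) {
    svm <- if (inherits(svs, "tx_svset")) svs$sv else as.matrix(svs)
    if (ncol(svm) > 0) {
      full <- cbind(X, svm)
      qrf <- qr(full)
      if (qrf$rank < ncol(full)) {
        drop_idx <- setdiff(seq_len(ncol(full)), qrf$pivot[seq_len(qrf$rank)])
        drop_idx <- drop_idx[drop_idx > ncol(X)]
        warning("dropping SV column(s) collinear with the design: ",
                paste(colnames(full)[drop_idx], collapse = ", "))
        full <- full[, setdiff(seq_len(ncol(full)), drop_idx), drop = FALSE]
      }
      X <- full
    }
  }
  X
}

# Vectorized per-feature OLS: Y features x samples, X samples x p.
.ols_fit <- function(Y, X) {
  qx <- qr(X)
  .assert(qx$rank == ncol(X), "design matrix is rank deficient")
  XtXinv <- chol2inv(qr.R(qx))
  B <- Y %*% X %*% XtXinv                 # features x p
  res <- Y - B %*% t(X)
  df <- ncol(Y) - ncol(X)
  .assert(df > 0, "no residual degrees of freedom")
  sigma2 <- rowSums(res^2) / df
  se <- sqrt(outer(sigma2, diag(XtXinv)))
  tval <- B / se
  pval <- 2 * stats::pt(-abs(tval), df)
  # noiseless features fit exactly: a non-zero coefficient is then certain
  exact <- se == 0
  if (any(exact)) pval[exact] <- ifelse(abs(B[exact]) > 1e-8, 0, 1)
  dimnames(B) <- dimnames(se) <- dimnames(tval) <- dimnames(pval) <-
    list(rownames(Y), colnames(X))
  list(coefficients = B, se = se, t = tval, p = pval, df = df,
       sigma2 = sigma2)
}

#' Fit the age-by-sex interaction model per feature
#'
#' Ordinary least squares of each normalized feature on sex (F = 0, M = 1),
#' age in years, their interaction, and any surrogate variables:
#' `y ~ mu + alpha sex + beta age + gamma sex:age + sum(delta_k SV_k)`.
#' Two-sided coefficient p-values use the t distribution on the residual
#' degrees of freedom. An interaction coefficient significantly different from
#' 0 flags an age-by-sex interaction.
#'
#' @param values features x samples matrix (or `tx_norm`), scaling-normalized.
#' @param samples data.frame with `sex`, `age`.
#' @param svs optional `tx_svset` or samples x k matrix.
#' @return object of class `tx_fit`: coefficient/se/t/p matrices (columns
#'   intercept, sex, age, sex_age, SV...), residual df.
#' @export
fit_interaction_model <- function(values, samples, svs = NULL) {
  Y <- .as_values(values)
  X <- .design_interaction(samples, svs)
  out <- .ols_fit(Y, X)
  out$model <- "interaction"
  class(out) <- "tx_fit"
  out
}

#' Call differential features from a fit plus effect-size gates
#'
#' A gene is called differential when the relevant coefficient has p < 0.05
#' AND the fold change of group-mean TPM exceeds 1.5 (direction-symmetric:
#' `max(m1/m2, m2/m1)`); a splice event when p < 0.05 AND the absolute
#' difference in group-mean PSI exceeds 0.05. Groups are old vs young
#' (age > 60 vs < 40) for the age coefficient and M vs F for sex. For the
#' interaction coefficient the call is on the p-value alone. Effect sizes are
#' computed on the raw (unnormalized) matrix; zero group-mean TPM triggers a
#' pseudocount, flagged in the output.
#'
#' @param fit a `tx_fit` (interaction or stratified).
#' @param raw raw TPM or PSI matrix aligned with the fit's features/samples.
#' @param samples sample data.frame.
#' @param data_type `"expression"` or `"splicing"`.
#' @param coefficient which coefficient drives the call: `"sex"`, `"age"` or
#'   `"interaction"`.
#' @param p_cutoff,fc_cutoff,dpsi_cutoff thresholds (defaults 0.05, 1.5, 0.05).
#' @param pseudocount added to zero group means for fold changes.
#' @return data.frame: feature, p, effect (fold change or delta PSI), called,
#'   pseudocount_used.
#' @export
call_differential <- function(fit, raw, samples,
                              data_type = c("expression", "splicing"),
                              coefficient = c("age", "sex", "interaction"),
                              p_cutoff = 0.05, fc_cutoff = 1.5,
                              dpsi_cutoff = 0.05, pseudocount = 0.01) {
  data_type <- match.arg(data_type)
  coefficient <- match.arg(coefficient)
  coef_col <- switch(coefficient, sex = "sex", age = "age",
                     interaction = "sex_age")
  if (!coef_col %in% colnames(fit$p) && coefficient == "age" &&
      "age" %in% colnames(fit$p)) coef_col <- "age"
  p <- fit$p[, coef_col]
  feats <- rownames(fit$p)
  raw <- raw[feats, , drop = FALSE]
  if (coefficient == "interaction") {
    out <- data.frame(feature = feats, p = p, effect = NA_real_,
                      called = p < p_cutoff, pseudocount_used = FALSE,
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    return(out)
  }
  grp <- if (coefficient == "sex") samples$sex else .age_group(samples$age)
  g1 <- !is.na(grp) & grp %in% c("M", "old")
  g2 <- !is.na(grp) & grp %in% c("F", "young")
  m1 <- rowMeans(raw[, g1, drop = FALSE])
  m2 <- rowMeans(raw[, g2, drop = FALSE])
  if (data_type == "expression") {
    ps_used <- (m1 == 0) | (m2 == 0)
    m1p <- ifelse(m1 == 0, pseudocount, m1)
    m2p <- ifelse(m2 == 0, pseudocount, m2)
    effect <- pmax(m1p / m2p, m2p / m1p)
    called <- p < p_cutoff & effect > fc_cutoff
  } else {
    ps_used <- rep(FALSE, length(m1))
    effect <- m1 - m2
    called <- p < p_cutoff & abs(effect) > dpsi_cutoff
  }
  out <- data.frame(feature = feats, p = p, effect = effect, called = called,
                    pseudocount_used = ps_used, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Permutation false-discovery estimation for the differential calls
#'
#' Sex and age labels are shuffled jointly (one donor-label permutation applied
#' to both) `n_perm` times; the model is refit and differential calls are made
#' inside each permutation with the original thresholds. Returns the
#' per-feature FDR (fraction of permutations in which the feature is falsely
#' called) and the per-iteration fraction of original calls that reappear.
#'
#' @param values normalized features x samples matrix (or `tx_norm`).
#' @param raw raw TPM/PSI matrix (effect-size gates).
#' @param samples sample data.frame.
#' @param svs optional surrogate variables (kept fixed across permutations; the
#'   data, and hence its latent structure, is unchanged by label shuffling).
#' @param data_type,coefficient,... passed to [call_differential()].
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return list: `fdr` (per-feature), `overlap_fraction` (per-iteration),
#'   `original` (the original call table).
#' @export
permutation_fdr <- function(values, raw, samples, svs = NULL,
                            data_type = "expression", coefficient = "age",
                            n_perm = 1000, seed = 1L, ...) {
  .assert(n_perm >= 100, "n_perm must be >= 100")
  fit0 <- fit_interaction_model(values, samples, svs)
  orig <- call_differential(fit0, raw, samples, data_type = data_type,
                            coefficient = coefficient, ...)
  called0 <- orig$feature[orig$called]
  set.seed(seed)
  n <- nrow(samples)
  hits <- stats::setNames(numeric(nrow(orig)), orig$feature)
  overlap <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    perm <- sample(n)
    sp <- samples
    sp$sex <- samples$sex[perm]
    sp$age <- samples$age[perm]
    fitb <- fit_interaction_model(values, sp, svs)
    cb <- call_differential(fitb, raw, sp, data_type = data_type,
                            coefficient = coefficient, ...)
    hits[cb$feature[cb$called]] <- hits[cb$feature[cb$called]] + 1
    overlap[b] <- if (length(called0))
      mean(called0 %in% cb$feature[cb$called]) else NA_real_
  }
  list(fdr = hits / n_perm, overlap_fraction = overlap, original = orig)
}

#' Fit sex-stratified age models and label sex-biased features
#'
#' Within each sex separately, fits `y ~ beta0 + beta_{F/M} age + sum(delta_k
#' SV_k)` per feature and calls age-associated features with the same p-value
#' and effect-size gates as the joint analysis. Features significant in exactly
#' one sex are labeled `female_specific`/`male_specific` (for splice events
#' these are the sBASEs); features significant in both are `common`.
#'
#' @param values normalized features x samples matrix (or `tx_norm`).
#' @param raw raw matrix for effect gates.
#' @param samples sample data.frame.
#' @param svs_by_sex optional named list `list(F = , M = )` of SV sets
#'   estimated within each sex.
#' @param data_type `"expression"` or `"splicing"`.
#' @param min_n minimum samples per sex stratum (default 10).
#' @param ... thresholds passed to [call_differential()].
#' @return list of class `tx_stratfit`: per-sex `tx_fit`s (`fits`), per-sex
#'   call tables (`calls`), and `labels` (feature, called_F, called_M, label).
#' @export
fit_sex_stratified_model <- function(values, raw, samples, svs_by_sex = NULL,
                                     data_type = "expression", min_n = 10, ...) {
  Y <- .as_values(values)
  fits <- list(); calls <- list()
  for (sx in c("F", "M")) {
    idx <- samples$sex == sx
    if (sum(idx) < min_n) {
      message("sex stratum ", sx, " below minimum size (", sum(idx), "); skipped")
      next
    }
    ss <- samples[idx, ]
    X <- cbind(intercept = 1, age = ss$age)
    svs <- svs_by_sex[[sx]]
    if (!is.null(svs)) {
      svm <- if (inherits(svs, "tx_svset")) svs$sv else as.matrix(svs)
      if (ncol(svm) > 0) X <- cbind(X, svm)
    }
    f <- .ols_fit(Y[, idx, drop = FALSE], X)
    f$model <- paste0("stratified_", sx)
    class(f) <- "tx_fit"
    fits[[sx]] <- f
    calls[[sx]] <- call_differential(f, raw[, idx, drop = FALSE], ss,
                                     data_type = data_type,
                                     coefficient = "age", ...)
  }
  labels <- NULL
  if (all(c("F", "M") %in% names(calls))) {
    cf <- calls$F$called; cm <- calls$M$called
    lab <- rep(NA_character_, length(cf))
    lab[cf & !cm] <- "female_specific"
    lab[!cf & cm] <- "male_specific"
    lab[cf & cm] <- "common"
    labels <- data.frame(feature = calls$F$feature, called_F = cf,
                         called_M = cm, beta_F = fits$F$coefficients[, "age"],
                         beta_M = fits$M$coefficients[, "age"], label = lab,
                         stringsAsFactors = FALSE)
  }
  structure(list(fits = fits, calls = calls, labels = labels,
                 data_type = data_type),
            class = "tx_stratfit")
}

#' Hypergeometric significance of a set overlap
#'
#' Upper-tail probability of observing at least the seen overlap between two
#' feature sets drawn from a common universe.
#'
#' @param set_a,set_b character vectors, subsets of `universe`.
#' @param universe character vector.
#' @return the p-value `P(X >= |A intersect B|)`.
#' @export
overlap_significance <- function(set_a, set_b, universe) {
  .assert(length(universe) > 0, "empty universe")
  .assert(all(set_a %in% universe) && all(set_b %in% universe),
          "sets must be subsets of the universe")
  k <- length(intersect(set_a, set_b))
  stats::phyper(k - 1, length(set_a), length(universe) - length(set_a),
                length(set_b), lower.tail = FALSE)
}

#' Correlation of per-sex age effects
#'
#' Spearman correlation between the female and male age coefficients over the
#' features fitted in both sexes.
#'
#' @param stratfit a `tx_stratfit`, or a data.frame with `beta_F`, `beta_M`.
#' @return list with `rho`, `p`, `n`.
#' @export
effect_size_correlation <- function(stratfit) {
  lab <- if (inherits(stratfit, "tx_stratfit")) stratfit$labels else stratfit
  .assert(!is.null(lab), "both sex strata are required")
  ok <- stats::complete.cases(lab[, c("beta_F", "beta_M")])
  .assert(sum(ok) >= 5, "need at least 5 paired coefficients")
  ct <- suppressWarnings(stats::cor.test(lab$beta_F[ok], lab$beta_M[ok],
                                         method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Paired comparison of GE vs AS effect correlations across tissues
#'
#' Wilcoxon signed-rank test on per-tissue pairs of Spearman rho values
#' (gene expression vs alternative splicing).
#'
#' @param rho_ge,rho_as numeric vectors of per-tissue correlations, aligned.
#' @return the `htest` object.
#' @export
compare_ge_as_correlations <- function(rho_ge, rho_as) {
  .assert(length(rho_ge) == length(rho_as), "vectors must be aligned by tissue")
  stats::wilcox.test(rho_ge, rho_as, paired = TRUE)
}

#' Compare two correlation coefficients (Fisher z)
#'
#' `z = (atanh r1 - atanh r2) / sqrt(1/(n1-3) + 1/(n2-3))` with a two-sided
#' normal p-value.
#'
#' @param r1,r2 correlation coefficients with `|r| < 1`.
#' @param n1,n2 sample sizes (> 3).
#' @return list with `z` and `p`.
#' @export
compare_correlations <- function(r1, n1, r2, n2) {
  .assert(abs(r1) < 1 && abs(r2) < 1, "|r| must be < 1")
  .assert(n1 > 3 && n2 > 3, "sample sizes must exceed 3")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Sampling-bias regression of differential counts on cohort size
#'
#' OLS of the per-tissue number of differential features on the number of
#' selected samples and the number of detected features, with tissues as
#' observations. Constant predictors are dropped with a note.
#'
#' @param n_differential,size,detected numeric vectors over tissues (>= 4).
#' @return list of class `tx_biasfit`: `coefficients`, `p`, `dropped`.
#' @export
sample_size_bias_model <- function(n_differential, size, detected) {
  .assert(length(n_differential) >= 4, "need at least 4 tissues")
  d <- data.frame(N = n_differential, Size = size, Detected = detected)
  dropped <- character(0)
  for (v in c("Size", "Detected")) {
    if (stats::sd(d[[v]]) == 0) {
      dropped <- c(dropped, v)
      d[[v]] <- NULL
    }
  }
  .assert(ncol(d) > 1, "all predictors are constant")
  if (length(dropped)) message("constant predictor(s) dropped: ",
                               paste(dropped, collapse = ", "))
  fit <- stats::lm(N ~ ., data = d)
  sm <- suppressWarnings(summary(fit))$coefficients
  structure(list(coefficients = sm[, "Estimate"], p = sm[, "Pr(>|t|)"],
                 dropped = dropped, fit = fit),
            class = "tx_biasfit")
}
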