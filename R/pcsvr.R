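#' Fit a PCA embedding for two groups of samples
#'
#' Features are centered (not variance-scaled; inputs are expected to be
#' AveDis-normalized upstream) and the samples projected on principal
#' components ordered by explained variance. The smallest prefix of PCs whose
#' cumulative explained variance strictly exceeds `variance_cutoff` is kept.
#'
#' @param values features x samples matrix (or `tx_norm`).
#' @param groups factor/character of length n_samples with exactly two levels.
#' @param variance_cutoff fraction of global variance to capture (default 0.8).
#' @return list with `scores` (samples x selected PCs), `groups`,
#'   `n_pcs`, `variance_captured`.
#' @export
fit_pca_embedding <- function(values, groups, variance_cutoff = 0.8) {
  values <- .as_values(values)
  groups <- as.factor(groups)
  .assert(nlevels(groups) == 2, "groups must have exactly two levels")
  .assert(min(table(groups)) >= 2, "need at least 2 samples per group")
  .assert(variance_cutoff > 0 && variance_cutoff < 1, "cutoff must be in (0,1)")
  X <- t(values)                       # samples x features
  X <- sweep(X, 2, colMeans(X))
  sv <- La.svd(X, nu = nrow(X), nv = 0)
  ev <- sv$d^2
  tot <- sum(ev)
  .assert(tot > 0, "matrix has no variance")
  cumfrac <- cumsum(ev) / tot
  k <- which(cumfrac > variance_cutoff)[1]
  scores <- sv$u[, seq_len(k), drop = FALSE] *
    rep(sv$d[seq_len(k)], each = nrow(X))
  rownames(scores) <- colnames(values)
  list(scores = scores, groups = groups, n_pcs = k,
       variance_captured = cumfrac[k])
}

#' Principal-component signal-to-variation ratio
#'
#' Computes `pcSVR(X, Y) = ||Xbar - Ybar||_2 / sqrt(s2_X/N_x + s2_Y/N_y)` on
#' the embedded PC scores, where `s2` is the mean squared Euclidean distance of
#' group members to their group mean (denominator N - 1). Values well above 1
#' indicate intrinsic between-group differences relative to within-group
#' dispersion.
#'
#' @param embedding output of [fit_pca_embedding()].
#' @return list of class `tx_pcsvr` with `pcsvr`, group means, dispersions and
#'   sizes.
#' @export
compute_pcsvr <- function(embedding) {
  g <- embedding$groups
  lv <- levels(g)
  xs <- embedding$scores[g == lv[1], , drop = FALSE]
  ys <- embedding$scores[g == lv[2], , drop = FALSE]
  xb <- colMeans(xs); yb <- colMeans(ys)
  s2x <- sum(sweep(xs, 2, xb)^2) / (nrow(xs) - 1)
  s2y <- sum(sweep(ys, 2, yb)^2) / (nrow(ys) - 1)
  .assert(s2x + s2y > 0, "zero within-group dispersion in both groups")
  structure(list(pcsvr = sqrt(sum((xb - yb)^2)) /
                   sqrt(s2x / nrow(xs) + s2y / nrow(ys)),
                 mean_x = xb, mean_y = yb, s2x = s2x, s2y = s2y,
                 n_x = nrow(xs), n_y = nrow(ys), n_pcs = embedding$n_pcs),
            class = "tx_pcsvr")
}

# one-shot statistic: PCA refit + pcSVR, lean path used inside permutation loops.
# M is samples x features; g logical (group 1 = TRUE).
.pcsvr_stat <- function(M, g, variance_cutoff = 0.8) {
  X <- sweep(M, 2, colMeans(M))
  sv <- La.svd(X, nu = nrow(X), nv = 0)
  ev <- sv$d^2
  cumfrac <- cumsum(ev) / sum(ev)
  k <- which(cumfrac > variance_cutoff)[1]
  S <- sv$u[, seq_len(k), drop = FALSE] * rep(sv$d[seq_len(k)], each = nrow(X))
  xs <- S[g, , drop = FALSE]; ys <- S[!g, , drop = FALSE]
  xb <- colMeans(xs); yb <- colMeans(ys)
  s2x <- sum(sweep(xs, 2, xb)^2) / (nrow(xs) - 1)
  s2y <- sum(sweep(ys, 2, yb)^2) / (nrow(ys) - 1)
  den <- s2x / nrow(xs) + s2y / nrow(ys)
  if (den <= 0) return(NA_real_)
  sqrt(sum((xb - yb)^2)) / sqrt(den)
}

#' pcSVR with an empirical permutation p-value
#'
#' The observed statistic is the mean pcSVR over `n_iter` labeled subsamples of
#' size `s = floor(0.5 * min(N_x, N_y))` drawn from each group. The null
#' distribution consists of `n_iter` label-free draws: `2s` samples are drawn
#' from the pooled stratum (without replacement for scheme `"subsample"`, with
#' replacement for `"bootstrap"`) and split at random into two pseudo-groups of
#' size `s`. PCA is refit on every draw so observed and null statistics face
#' identical estimation noise. The empirical p-value is the fraction of null
#' values strictly greater than the observed mean; a p of 0 is reported as 0
#' with resolution bound `1/n_iter`.
#'
#' @param values features x samples matrix (or `tx_norm`).
#' @param groups two-level factor/character over samples.
#' @param scheme `"subsample"` or `"bootstrap"` (null draw scheme).
#' @param n_iter iterations for both the observed mean and the null.
#' @param variance_cutoff PC cumulative-variance cutoff.
#' @param seed integer seed.
#' @return list of class `tx_pcsvr_test`: `pcsvr` (observed mean),
#'   `null_values`, `empirical_p`, `resolution`, `settings`.
#' @export
pcsvr_test <- function(values, groups, scheme = c("subsample", "bootstrap"),
                       n_iter = 10000, variance_cutoff = 0.8, seed = 1L) {
  scheme <- match.arg(scheme)
  values <- .as_values(values)
  groups <- as.factor(groups)
  .assert(nlevels(groups) == 2, "groups must have exactly two levels")
  sizes <- table(groups)
  .assert(min(sizes) >= 4, "each group needs at least 4 samples")
  s <- floor(0.5 * min(sizes))
  M <- t(values)
  ix <- which(groups == levels(groups)[1])
  iy <- which(groups == levels(groups)[2])
  n <- nrow(M)
  set.seed(seed)
  obs <- numeric(n_iter)
  nul <- numeric(n_iter)
  glab <- rep(c(TRUE, FALSE), each = s)
  for (t in seq_len(n_iter)) {
    sub <- c(sample(ix, s), sample(iy, s))
    obs[t] <- .pcsvr_stat(M[sub, , drop = FALSE], glab, variance_cutoff)
    draw <- if (scheme == "subsample") sample(n, 2 * s)
            else sample(n, 2 * s, replace = TRUE)
    nul[t] <- .pcsvr_stat(M[draw, , drop = FALSE], sample(glab), variance_cutoff)
  }
  obs_mean <- mean(obs, na.rm = TRUE)
  nul_ok <- nul[!is.na(nul)]
  structure(list(pcsvr = obs_mean, null_values = nul,
                 empirical_p = mean(nul_ok > obs_mean),
                 resolution = 1 / n_iter,
                 settings = list(scheme = scheme, n_iter = n_iter,
                                 variance_cutoff = variance_cutoff,
                                 subsample_size = s, seed = seed)),
            class = "tx_pcsvr_test")
}

#' Screen all tissue strata for sex or age pcSVR
#'
#' For each tissue and data type (GE on log2(TPM+1), AS on PSI) computes the
#' pcSVR between sexes (F vs M) or between age groups (young < 40 vs old > 60,
#' middle ages excluded) with its empirical p-value. Features on sex
#' chromosomes (genes, or events whose host gene is on chrX/chrY) can be
#' excluded. Strata with fewer than `min_group` samples in either group are
#' flagged skipped.
#'
#' @param cohort a `tx_cohort`.
#' @param contrast `"sex"` or `"age"`.
#' @param exclude_sex_chromosomes drop chrX/chrY features before PCA.
#' @param n_iter,variance_cutoff,scheme,seed passed to [pcsvr_test()].
#' @param p_cutoff significance flag threshold on the empirical p (default 0.1).
#' @param min_group minimum samples per group (default 4).
#' @param sex_stratum optionally restrict to one sex before an age contrast
#'   (`"F"` or `"M"`), for sex-specific age-effect comparisons.
#' @return data.frame with one row per tissue x data type: statistic, p,
#'   significance flag, group sizes, skip reason.
#' @export
pcsvr_screen <- function(cohort, contrast = c("sex", "age"),
                         exclude_sex_chromosomes = FALSE,
                         n_iter = 1000, variance_cutoff = 0.8,
                         scheme = "subsample", seed = 1L, p_cutoff = 0.1,
                         min_group = 4, sex_stratum = NULL) {
  contrast <- match.arg(contrast)
  feats <- cohort$features
  sexchr_genes <- feats$feature_id[feats$kind == "gene" &
                                     feats$chromosome %in% c("chrX", "chrY")]
  sexchr_events <- feats$feature_id[feats$kind == "event" &
                                      feats$chromosome %in% c("chrX", "chrY")]
  rows <- list()
  for (tis in unique(cohort$samples$tissue)) {
    in_t <- cohort$samples$tissue == tis
    s <- cohort$samples[in_t, ]
    if (!is.null(sex_stratum)) s <- s[s$sex == sex_stratum, ]
    grp <- if (contrast == "sex") s$sex else .age_group(s$age)
    keep <- !is.na(grp)
    s <- s[keep, ]; grp <- grp[keep]
    for (dt in c("GE", "AS")) {
      mat <- if (dt == "GE") log2(cohort$tpm[, s$sample_id, drop = FALSE] + 1)
             else cohort$psi[, s$sample_id, drop = FALSE]
      if (dt == "AS" && anyNA(mat)) {
        cc <- stats::complete.cases(mat)
        mat <- mat[cc, , drop = FALSE]
      }
      if (exclude_sex_chromosomes) {
        drop_ids <- if (dt == "GE") sexchr_genes else sexchr_events
        mat <- mat[!rownames(mat) %in% drop_ids, , drop = FALSE]
      }
      sdv <- apply(mat, 1, stats::sd)
      mat <- mat[sdv > 0, , drop = FALSE]
      tab <- table(factor(grp, levels = unique(grp)))
      if (length(tab) < 2 || min(tab) < min_group || nrow(mat) < 2) {
        rows[[length(rows) + 1]] <- data.frame(
          tissue = tis, data_type = dt, contrast = contrast,
          n1 = if (length(tab) >= 1) as.integer(tab[1]) else 0L,
          n2 = if (length(tab) >= 2) as.integer(tab[2]) else 0L,
          pcsvr = NA_real_, p = NA_real_, significant = NA,
          skipped = TRUE, reason = "group below minimum size",
          stringsAsFactors = FALSE)
        next
      }
      nv <- normalize_scaling(mat)
      res <- pcsvr_test(nv, grp, scheme = scheme, n_iter = n_iter,
                        variance_cutoff = variance_cutoff, seed = seed)
      tab <- table(grp)
      rows[[length(rows) + 1]] <- data.frame(
        tissue = tis, data_type = dt, contrast = contrast,
        n1 = as.integer(tab[1]), n2 = as.integer(tab[2]),
        pcsvr = res$pcsvr, p = res$empirical_p,
        significant = res$empirical_p < p_cutoff,
        skipped = FALSE, reason = NA_character_, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
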