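#' Remove surrogate-variable contributions and average by sex and age
#'
#' Subtracts the fitted SV contributions from each feature while protecting the
#' sex, age and age-by-sex effects, then averages samples sharing the same
#' (sex, age in whole years). Ages observed in only one sex are present only
#' for that sex.
#'
#' @param values features x samples matrix (or `tx_norm`).
#' @param samples data.frame with `sex`, `age`.
#' @param svs a `tx_svset` or samples x k matrix; zero columns = no correction.
#' @return list: `corrected` (features x samples), `trajectories` (per sex, a
#'   features x ages matrix with the age grid as column names), `ages` (per
#'   sex, sorted integer ages).
#' @export
correct_confounders_and_average <- function(values, samples, svs = NULL) {
  Y <- .as_values(values)
  svm <- if (inherits(svs, "tx_svset")) svs$sv else svs
  if (!is.null(svm) && ncol(svm) > 0) {
    design <- stats::model.matrix(~ sex * age,
                                  data.frame(sex = .sex01(samples$sex),
                                             age = samples$age))
    # single-sex strata make sex terms inestimable; keep the identifiable part
    keep <- c(TRUE, apply(design[, -1, drop = FALSE], 2,
                          function(x) stats::sd(x) > 0))
    design <- design[, keep, drop = FALSE]
    qd <- qr(design)
    design <- design[, qd$pivot[seq_len(qd$rank)], drop = FALSE]
    Y <- limma::removeBatchEffect(Y, covariates = svm, design = design)
  }
  traj <- list(); ages <- list()
  for (sx in c("F", "M")) {
    idx <- which(samples$sex == sx)
    if (!length(idx)) next
    ag <- sort(unique(samples$age[idx]))
    m <- vapply(ag, function(a) {
      cols <- idx[samples$age[idx] == a]
      rowMeans(Y[, cols, drop = FALSE])
    }, numeric(nrow(Y)))
    m <- matrix(m, nrow = nrow(Y), dimnames = list(rownames(Y), ag))
    traj[[sx]] <- m
    ages[[sx]] <- ag
  }
  list(corrected = Y, trajectories = traj, ages = ages)
}

# KPSS level-stationarity statistic (Bartlett long-run variance, short
# bandwidth trunc(3*sqrt(n)/13)); 5% critical value 0.463.
.kpss_stat <- function(x) {
  n <- length(x)
  e <- x - mean(x)
  S <- cumsum(e)
  l <- trunc(3 * sqrt(n) / 13)
  s2 <- sum(e^2) / n
  if (l > 0) for (k in seq_len(l))
    s2 <- s2 + 2 * (1 - k / (l + 1)) * sum(e[(k + 1):n] * e[1:(n - k)]) / n
  if (s2 <= 0) return(0)
  sum(S^2) / (n^2 * s2)
}

.choose_d <- function(x, d_max = 2, crit = 0.463) {
  for (d in 0:d_max) {
    y <- if (d > 0) diff(x, differences = d) else x
    if (.kpss_stat(y) < crit) return(d)
  }
  d_max
}

# best ARIMA at KPSS-chosen d, minimizing AIC over (p, q) in 0..p_max/q_max
.fit_arima_best <- function(x, p_max = 2, q_max = 2, d_max = 2) {
  d <- .choose_d(x, d_max)
  best <- NULL; best_pq <- c(NA, NA)
  for (p in 0:p_max) for (q in 0:q_max) {
    f <- tryCatch(suppressWarnings(stats::arima(x, order = c(p, d, q),
                                                method = "ML")),
                  error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || stats::AIC(f) < stats::AIC(best))) {
      best <- f; best_pq <- c(p, q)
    }
  }
  list(fit = best, p = best_pq[1], d = d, q = best_pq[2])
}

#' Select features with a chronological trend by ARIMA model selection
#'
#' Per feature, fits the per-age mean trajectory with an ARIMA model: the
#' differencing order d is chosen first by successive KPSS level-stationarity
#' tests (5% level), then the (p, q) orders by minimum AIC over a bounded grid
#' (the Hyndman-Khandakar scheme). A feature is retained when the selected
#' model has d >= 1 and the sum of absolute AR and MA coefficients is positive
#' (at least one non-zero AR or MA term). Constant trajectories are excluded,
#' not errors.
#'
#' @param trajectories features x ages matrix (per-age means for one sex),
#'   column names the sorted ages; >= 20 age points.
#' @param p_max,q_max,d_max order grid bounds.
#' @return list of class `tx_chron`: `table` (per-feature orders, coefficient
#'   sum, AIC, keep flag), `selected` (kept feature ids), `fitted` (features x
#'   ages matrix of ARIMA-fitted levels for all non-constant features).
#' @export
select_chronological_features <- function(trajectories, p_max = 2, q_max = 2,
                                          d_max = 2) {
  .assert(ncol(trajectories) >= 20, "trajectory length must be >= 20 age points")
  feats <- rownames(trajectories)
  tab <- data.frame(feature = feats, p = NA_integer_, d = NA_integer_,
                    q = NA_integer_, coef_sum = NA_real_, aic = NA_real_,
                    keep = FALSE, stringsAsFactors = FALSE)
  fitted <- matrix(NA_real_, nrow(trajectories), ncol(trajectories),
                   dimnames = dimnames(trajectories))
  for (i in seq_along(feats)) {
    x <- trajectories[i, ]
    if (stats::sd(x) == 0) next
    bf <- .fit_arima_best(x, p_max, q_max, d_max)
    if (is.null(bf$fit)) next
    cs <- sum(abs(bf$fit$coef[grepl("^(ar|ma)", names(bf$fit$coef))]))
    tab$p[i] <- bf$p; tab$d[i] <- bf$d; tab$q[i] <- bf$q
    tab$coef_sum[i] <- cs
    tab$aic[i] <- stats::AIC(bf$fit)
    tab$keep[i] <- bf$d >= 1 && cs > 0
    fitted[i, ] <- x - stats::residuals(bf$fit)
  }
  structure(list(table = tab, selected = feats[tab$keep], fitted = fitted),
            class = "tx_chron")
}

# exact Pillai/Hotelling p-value for a two-group MANOVA on the score matrix;
# equivalent to stats::manova with test = "Pillai" for two groups.
.two_group_manova_p <- function(A, B) {
  nA <- nrow(A); nB <- nrow(B); p <- ncol(A)
  n <- nA + nB
  if (n - p - 1 <= 0) return(NA_real_)
  d <- colMeans(A) - colMeans(B)
  SA <- crossprod(sweep(A, 2, colMeans(A)))
  SB <- crossprod(sweep(B, 2, colMeans(B)))
  S <- (SA + SB) / (n - 2)
  Sinv <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(Sinv)) return(NA_real_)
  T2 <- (nA * nB / n) * drop(t(d) %*% Sinv %*% d)
  Fstat <- (n - p - 1) / (p * (n - 2)) * T2
  stats::pf(Fstat, p, n - p - 1, lower.tail = FALSE)
}

# loess smooth y over x at the same x, with the span floored so the local
# neighbourhood always holds enough points; returns y unchanged if too short
.loess_smooth <- function(x, y, span) {
  n <- length(x)
  if (n < 7) return(y)
  span_eff <- max(span, min(1, 5 / n))
  fit <- suppressWarnings(stats::loess(y ~ x, span = span_eff, degree = 1,
                                       family = "gaussian"))
  stats::predict(fit, newdata = data.frame(x = x))
}

#' Sliding-window MANOVA aging-rate curve
#'
#' For every window span `w` and age `i`, the samples aged in `(i-w, i]` are
#' compared with those in `(i, i+w]` by a MANOVA (Pillai trace) on the top-3
#' principal-component scores of the chronological-feature submatrix (PCA fit
#' once on all stratum samples so per-age statistics share a basis). Per span,
#' the `-log10 p` series is LOESS-smoothed at each bandwidth in `spans`,
#' averaged across bandwidths, then smoothed once more at bandwidth 0.5; the
#' final rate at each age is the mean across window spans, floored at 0.
#'
#' @param corrected features x samples matrix (confounder-corrected).
#' @param ages sample ages in years.
#' @param chronological character vector of chronological feature ids (>= 3).
#' @param w_range integer window spans in years (default 5:15).
#' @param spans LOESS bandwidth grid (default seq(0.25, 0.75, 0.05)).
#' @param n_pcs PCs entering the MANOVA (default 3).
#' @param min_flank minimum samples per flanking window (default 3).
#' @param age_grid ages at which to evaluate; defaults to all integer ages
#'   spanned by the data.
#' @return list of class `tx_ratecurve`: `ages`, `rate`, `raw` (spans x ages
#'   matrix of unsmoothed -log10 p), `settings`.
#' @export
compute_rate_curve <- function(corrected, ages, chronological,
                               w_range = 5:15, spans = seq(0.25, 0.75, 0.05),
                               n_pcs = 3, min_flank = 3, age_grid = NULL) {
  .assert(length(chronological) >= n_pcs,
          sprintf("chronological set must hold at least %d features", n_pcs))
  .assert(all(chronological %in% rownames(corrected)),
          "chronological features missing from the matrix")
  M <- t(corrected[chronological, , drop = FALSE])
  M <- sweep(M, 2, colMeans(M))
  sv <- La.svd(M, nu = nrow(M), nv = 0)
  k <- min(n_pcs, sum(sv$d > 1e-12))
  .assert(k >= n_pcs, "matrix rank insufficient for the requested PCs")
  scores <- sv$u[, seq_len(k), drop = FALSE] * rep(sv$d[seq_len(k)], each = nrow(M))
  if (is.null(age_grid))
    age_grid <- seq(min(ages), max(ages))
  raw <- matrix(NA_real_, length(w_range), length(age_grid),
                dimnames = list(w_range, age_grid))
  for (wi in seq_along(w_range)) {
    w <- w_range[wi]
    for (ai in seq_along(age_grid)) {
      i <- age_grid[ai]
      left <- which(ages > i - w & ages <= i)
      right <- which(ages > i & ages <= i + w)
      if (length(left) < min_flank || length(right) < min_flank) next
      pv <- .two_group_manova_p(scores[left, , drop = FALSE],
                                scores[right, , drop = FALSE])
      if (!is.na(pv)) raw[wi, ai] <- -log10(max(pv, 1e-300))
    }
  }
  per_w <- matrix(NA_real_, length(w_range), length(age_grid))
  for (wi in seq_along(w_range)) {
    ok <- !is.na(raw[wi, ])
    if (sum(ok) < 5) next
    x <- age_grid[ok]; y <- raw[wi, ok]
    sm <- rowMeans(sapply(spans, function(sp) .loess_smooth(x, y, sp)))
    per_w[wi, ok] <- .loess_smooth(x, sm, 0.5)
  }
  rate <- colMeans(per_w, na.rm = TRUE)
  rate[is.nan(rate)] <- NA_real_
  keep <- !is.na(rate)
  structure(list(ages = age_grid[keep], rate = pmax(rate[keep], 0),
                 raw = raw,
                 settings = list(w_range = w_range, spans = spans,
                                 n_pcs = n_pcs, min_flank = min_flank)),
            class = "tx_ratecurve")
}

#' Detect aging breakpoints on a rate curve
#'
#' The global maximum of the curve (endpoints excluded; ties broken by the
#' earliest age) is always a breakpoint. Each additional interior local
#' maximum `m` qualifies iff `(rate[m] - rate[nearest local minimum]) /
#' rate[global max] > 0.10`. Curve endpoints may serve as the nearest minimum
#' but never as breakpoints.
#'
#' @param curve a `tx_ratecurve`, or a list/data.frame with `ages` and `rate`.
#' @return list of class `tx_breakpoints`: data.frame `breakpoints` (age, rate,
#'   type in global_max/local_max) possibly empty.
#' @export
detect_breakpoints <- function(curve) {
  ages <- curve$ages; rate <- curve$rate
  .assert(length(rate) >= 5, "curve must have at least 5 points")
  n <- length(rate)
  if (length(unique(rate)) == 1) {
    warning("rate curve is flat; no breakpoints")
    return(structure(list(breakpoints = data.frame(age = numeric(0),
                                                   rate = numeric(0),
                                                   type = character(0))),
                     class = "tx_breakpoints"))
  }
  interior <- 2:(n - 1)
  is_max <- vapply(interior, function(i)
    rate[i] > rate[i - 1] && rate[i] >= rate[i + 1], logical(1))
  maxima <- interior[is_max]
  is_min <- vapply(interior, function(i)
    rate[i] <= rate[i - 1] && rate[i] <= rate[i + 1], logical(1))
  minima <- c(1, interior[is_min], n)   # endpoints may act as minima
  if (!length(maxima)) {
    warning("no interior local maximum; no breakpoints")
    return(structure(list(breakpoints = data.frame(age = numeric(0),
                                                   rate = numeric(0),
                                                   type = character(0))),
                     class = "tx_breakpoints"))
  }
  g <- maxima[which.max(rate[maxima])]  # which.max -> earliest on ties
  rows <- data.frame(age = ages[g], rate = rate[g], type = "global_max",
                     stringsAsFactors = FALSE)
  for (m in setdiff(maxima, g)) {
    nm <- minima[which.min(abs(ages[minima] - ages[m]))]
    if ((rate[m] - rate[nm]) / rate[g] > 0.10)
      rows <- rbind(rows, data.frame(age = ages[m], rate = rate[m],
                                     type = "local_max"))
  }
  rows <- rows[order(rows$age), ]
  rownames(rows) <- NULL
  structure(list(breakpoints = rows), class = "tx_breakpoints")
}

#' Compare female and male aging-rate curves
#'
#' Wilcoxon signed-rank test on paired per-age rates over the shared age grid
#' (zero differences dropped), plus each sex's major breakpoint (the global
#' maximum of its curve).
#'
#' @param curve_f,curve_m `tx_ratecurve` objects.
#' @return list: `p`, `statistic`, `n_shared`, `major_f`, `major_m` (age and
#'   rate of each sex's major breakpoint), `note`.
#' @export
compare_sex_rate_curves <- function(curve_f, curve_m) {
  shared <- intersect(curve_f$ages, curve_m$ages)
  if (length(shared) < 5) {
    message("fewer than 5 shared ages; comparison not performed")
    return(list(p = NA_real_, statistic = NA_real_, n_shared = length(shared),
                major_f = NULL, major_m = NULL, note = "insufficient shared ages"))
  }
  rf <- curve_f$rate[match(shared, curve_f$ages)]
  rm_ <- curve_m$rate[match(shared, curve_m$ages)]
  note <- NA_character_
  d <- rm_ - rf
  d <- d[d != 0]
  if (!length(d)) {
    p <- NA_real_; stat <- NA_real_
    note <- "curves identical; signed-rank test undefined (no difference)"
  } else if (all(d > 0) || all(d < 0)) {
    # one-signed differences sit at the extreme of the signed-rank null even
    # when tied in magnitude: exact two-sided p = 2 * 2^-n (capped at 1)
    p <- min(1, 2^(1 - length(d)))
    stat <- if (all(d > 0)) length(d) * (length(d) + 1) / 2 else 0
  } else {
    wt <- suppressWarnings(stats::wilcox.test(rm_, rf, paired = TRUE))
    p <- wt$p.value; stat <- unname(wt$statistic)
  }
  bf <- detect_breakpoints(curve_f)$breakpoints
  bm <- detect_breakpoints(curve_m)$breakpoints
  major <- function(b) if (nrow(b)) b[b$type == "global_max", c("age", "rate")] else NULL
  list(p = p, statistic = stat, n_shared = length(shared),
       major_f = major(bf), major_m = major(bm), note = note)
}
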