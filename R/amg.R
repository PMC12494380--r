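#' Disturbance iterations for aging-modulated gene discovery
#'
#' Randomly trims 20% (floor, minimum 1) of the chronological gene set
#' `n_iter` times; each iteration recomputes the aging-rate curve on the
#' retained genes and compares it with the original curve by a two-sided
#' Wilcoxon signed-rank test. Iterations with p < 0.05 significantly alter the
#' aging rate.
#'
#' The paired comparison uses the raw per-(window, age) `-log10 p` values with
#' each set normalized to its mean. Removing features necessarily shrinks the
#' rate statistic globally (fewer features average away less noise in the PC
#' scores), so a comparison of absolute levels flags every trim regardless of
#' which genes were removed; mean normalization makes the test sensitive to
#' changes in the temporal pattern of the aging rate — a collapsing or moving
#' peak — which is the disturbance the procedure is after. The smoothed curves
#' are too strongly autocorrelated for a rank test, hence the raw cells.
#'
#' @param corrected features x samples matrix (confounder-corrected).
#' @param ages sample ages in years.
#' @param chronological chronological gene ids (> 10).
#' @param n_iter iterations (default 200).
#' @param trim removal fraction (default 0.20).
#' @param seed integer seed.
#' @param ... passed to [compute_rate_curve()] (window grid, spans, ...).
#' @return list of class `tx_disturbance`: `removed` (list of id vectors per
#'   iteration), `p` (per iteration), `significant`, `original`
#'   (the untrimmed `tx_ratecurve`), `chronological`.
#' @export
disturbance_iterations <- function(corrected, ages, chronological,
                                   n_iter = 200, trim = 0.20, seed = 1L, ...) {
  .assert(length(chronological) > 10,
          "chronological set must hold more than 10 genes")
  original <- compute_rate_curve(corrected, ages, chronological, ...)
  n_rm <- max(1L, floor(trim * length(chronological)))
  set.seed(seed)
  removed <- vector("list", n_iter)
  pvals <- numeric(n_iter)
  a0 <- as.vector(original$raw)
  for (b in seq_len(n_iter)) {
    rm_ids <- sample(chronological, n_rm)
    removed[[b]] <- rm_ids
    cv <- compute_rate_curve(corrected, ages, setdiff(chronological, rm_ids), ...)
    d0 <- as.vector(cv$raw)
    ok <- !is.na(a0) & !is.na(d0)
    a <- a0[ok]; d <- d0[ok]
    pvals[b] <- if (sum(ok) < 2 || all(a == d) || mean(a) == 0 || mean(d) == 0) 1
      else suppressWarnings(stats::wilcox.test(d / mean(d), a / mean(a),
                                               paired = TRUE))$p.value
  }
  structure(list(removed = removed, p = pvals, significant = pvals < 0.05,
                 original = original, chronological = chronological,
                 settings = list(n_iter = n_iter, trim = trim, seed = seed)),
            class = "tx_disturbance")
}

#' Call aging-modulated genes from disturbance records
#'
#' Per gene, builds the 2x2 table of (removed vs kept) x (iteration
#' significant vs not) and tests enrichment of removal among significant
#' iterations with a one-sided Fisher exact test; AMGs have p < 0.05. Genes
#' never removed in any iteration are excluded with a warning.
#'
#' @param records a `tx_disturbance` (>= 50 iterations).
#' @param p_cutoff AMG threshold (default 0.05).
#' @return data.frame: gene, removed_sig, removed_nonsig, kept_sig,
#'   kept_nonsig, p, amg.
#' @export
call_amgs <- function(records, p_cutoff = 0.05) {
  n_iter <- length(records$p)
  .assert(n_iter >= 50, "need at least 50 iterations")
  sig <- records$significant
  genes <- records$chronological
  rm_mat <- sapply(records$removed, function(ids) genes %in% ids)  # genes x iter
  never <- rowSums(rm_mat) == 0
  if (any(never)) {
    warning(sum(never), " gene(s) never removed in any iteration; excluded")
    genes <- genes[!never]
    rm_mat <- rm_mat[!never, , drop = FALSE]
  }
  out <- data.frame(gene = genes,
                    removed_sig = as.integer(rm_mat %*% sig),
                    removed_nonsig = as.integer(rm_mat %*% !sig),
                    stringsAsFactors = FALSE)
  out$kept_sig <- sum(sig) - out$removed_sig
  out$kept_nonsig <- sum(!sig) - out$removed_nonsig
  out$p <- vapply(seq_len(nrow(out)), function(i) {
    tab <- matrix(c(out$removed_sig[i], out$removed_nonsig[i],
                    out$kept_sig[i], out$kept_nonsig[i]), 2, byrow = TRUE)
    stats::fisher.test(tab, alternative = "greater")$p.value
  }, numeric(1))
  out$amg <- out$p < p_cutoff
  out
}

#' Classify age-window expression patterns
#'
#' Averages ARIMA-fitted expression levels within nine 5-year age windows
#' (20-25, 26-30, ..., 61-65) and labels each gene: `up_at_young` iff the mean
#' fitted level over ages 31-40 strictly exceeds the mean over 20-30;
#' `monotone_decline` iff the window means are non-increasing. Genes whose
#' trajectory does not cover a required window stay unlabeled (NA).
#'
#' @param fitted features x ages matrix of ARIMA-fitted levels (column names
#'   are ages), e.g. the `fitted` element of [select_chronological_features()].
#' @return data.frame: gene, the nine window means, up_at_young,
#'   monotone_decline.
#' @export
classify_expression_patterns <- function(fitted) {
  ages <- as.numeric(colnames(fitted))
  lo <- c(20, 26, 31, 36, 41, 46, 51, 56, 61)
  hi <- c(25, 30, 35, 40, 45, 50, 55, 60, 65)
  wm <- sapply(seq_along(lo), function(w) {
    cols <- which(ages >= lo[w] & ages <= hi[w])
    if (!length(cols)) return(rep(NA_real_, nrow(fitted)))
    rowMeans(fitted[, cols, drop = FALSE])
  })
  colnames(wm) <- sprintf("w%d_%d", lo, hi)
  young <- rowMeans(wm[, 1:2, drop = FALSE])   # ages 20-30
  mid <- rowMeans(wm[, 3:4, drop = FALSE])     # ages 31-40
  up_at_young <- ifelse(is.na(young) | is.na(mid), NA, mid > young)
  mono <- apply(wm, 1, function(x)
    if (anyNA(x)) NA else all(diff(x) <= 0))
  data.frame(gene = rownames(fitted), wm, up_at_young = up_at_young,
             monotone_decline = mono, stringsAsFactors = FALSE,
             row.names = NULL)
}
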