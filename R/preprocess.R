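#' Filter lowly expressed genes
#'
#' Removes genes whose average TPM across samples is below 1; a gene with mean
#' exactly 1 is retained (removal is strict: mean < 1).
#'
#' @param tpm non-negative genes x samples matrix.
#' @return list with `retained` (gene ids) and `report` (a filter report).
#' @export
filter_genes <- function(tpm) {
  .assert(is.matrix(tpm) && nrow(tpm) > 0 && ncol(tpm) > 0, "empty TPM matrix")
  m <- rowMeans(tpm)
  keep <- !(m < 1)
  if (!any(keep)) warning("all genes fall below the average-TPM threshold")
  list(retained = rownames(tpm)[keep],
       report = list(rule = "average TPM < 1", input = nrow(tpm),
                     removed = sum(!keep), retained = sum(keep),
                     removed_ids = rownames(tpm)[!keep]))
}

#' Filter samples by PSI missingness
#'
#' Drops samples with missing PSI values in more than 50% of events (strictly
#' more; a sample missing exactly half is retained).
#'
#' @param psi events x samples matrix with NAs for missing values.
#' @return list with `retained` (sample ids) and `report`.
#' @export
filter_samples_by_missingness <- function(psi) {
  frac <- colMeans(is.na(psi))
  keep <- !(frac > 0.5)
  list(retained = colnames(psi)[keep],
       report = list(rule = "missing PSI > 50% of events", input = ncol(psi),
                     removed = sum(!keep), retained = sum(keep),
                     removed_ids = colnames(psi)[!keep]))
}

#' Filter splice events by the seven quantification-quality rules
#'
#' An event is retained iff all of: (1) missing PSI in fewer than 5% of
#' samples; (2) average junction counts (spliced-in + spliced-out) above 10;
#' (3) non-constant PSI across samples; (4) max(PSI) - min(PSI) above 0.05;
#' (5) PSI standard deviation above 0.01; (6) average PSI within [0.05, 0.95];
#' (7) host-gene average TPM above 1. All inequalities are strict as stated.
#' The report names the first failing rule per removed event.
#'
#' @param psi,junction_counts events x samples matrices (aligned).
#' @param tpm genes x samples matrix.
#' @param gene_map named character: event id -> host gene id.
#' @return list with `retained` (event ids) and `report` (per-rule counts and
#'   the first failing rule per removed event).
#' @export
filter_splice_events <- function(psi, junction_counts, tpm, gene_map) {
  ev <- rownames(psi)
  .assert(all(ev %in% names(gene_map)), "event(s) with no host-gene mapping")
  .assert(all(gene_map[ev] %in% rownames(tpm)),
          "host gene(s) missing from the TPM matrix")
  gene_mean <- rowMeans(tpm)
  rules <- c("missing>=5%", "mean JC<=10", "constant PSI", "range<=0.05",
             "SD<=0.01", "mean PSI outside [0.05,0.95]", "gene TPM<=1")
  first_fail <- rep(NA_character_, length(ev))
  for (i in seq_along(ev)) {
    x <- psi[i, ]
    obs <- x[!is.na(x)]
    s <- stats::sd(obs)
    fails <- c(mean(is.na(x)) >= 0.05,
               !(mean(junction_counts[i, ]) > 10),
               is.na(s) || s == 0,
               !(max(obs) - min(obs) > 0.05),
               !(isTRUE(s > 0.01)),
               {mm <- mean(obs); mm < 0.05 || mm > 0.95},
               !(gene_mean[gene_map[ev[i]]] > 1))
    if (any(fails)) first_fail[i] <- rules[which(fails)[1]]
  }
  keep <- is.na(first_fail)
  list(retained = ev[keep],
       report = list(input = length(ev), removed = sum(!keep),
                     retained = sum(keep),
                     first_failing_rule = stats::setNames(first_fail[!keep], ev[!keep]),
                     rule_counts = table(first_fail[!keep])))
}

#' Impute missing PSI values by k-nearest neighbours
#'
#' Each missing entry is replaced by the unweighted mean PSI of the k nearest
#' samples (Euclidean distance over jointly observed events, normalized by the
#' number of shared events) among samples observed at that event. If fewer than
#' k eligible neighbours exist, k is reduced with a warning. Observed entries
#' are never altered; imputed values are clamped to [0, 1].
#'
#' @param psi events x samples matrix with NAs.
#' @param k neighbour count (default 10).
#' @return a complete events x samples matrix.
#' @export
impute_missing_psi <- function(psi, k = 10) {
  if (!anyNA(psi)) return(psi)
  ns <- ncol(psi)
  obs <- !is.na(psi)
  # pairwise mean squared difference over shared events
  d2 <- matrix(Inf, ns, ns)
  for (a in seq_len(ns - 1)) for (b in (a + 1):ns) {
    sh <- obs[, a] & obs[, b]
    if (any(sh)) d2[a, b] <- d2[b, a] <- mean((psi[sh, a] - psi[sh, b])^2)
  }
  out <- psi
  reduced <- FALSE
  for (j in seq_len(ns)) {
    miss_ev <- which(!obs[, j])
    if (!length(miss_ev)) next
    ord <- order(d2[, j])
    ord <- ord[ord != j & is.finite(d2[ord, j])]
    for (i in miss_ev) {
      elig <- ord[obs[i, ord]]
      kk <- min(k, length(elig))
      if (kk < k) reduced <- TRUE
      .assert(kk >= 1, "no observed neighbour available for imputation")
      out[i, j] <- .clamp(mean(psi[i, elig[seq_len(kk)]]), 0, 1)
    }
  }
  if (reduced) warning("fewer than k complete neighbours for some entries; k reduced")
  out
}

#' Merge brain-region samples into functional-region pseudo-samples
#'
#' For each donor and functional region, produces one pseudo-sample whose
#' TPM/PSI/junction-count values are the arithmetic mean over that donor's
#' available member-region samples (missing PSI values ignored in the mean).
#' Donors with no member region present contribute nothing.
#'
#' @param cohort a `tx_cohort` whose samples are brain-region samples.
#' @param region_map named character: tissue label -> functional region. Every
#'   tissue present in the cohort must be mapped.
#' @return a `tx_cohort` of pseudo-samples (tissue = functional region).
#' @export
merge_brain_regions <- function(cohort, region_map) {
  s <- cohort$samples
  missing_t <- setdiff(unique(s$tissue), names(region_map))
  .assert(length(missing_t) == 0,
          paste("tissue(s) absent from region_map:", paste(missing_t, collapse = ", ")))
  s$region <- region_map[s$tissue]
  key <- paste(s$donor, s$region, sep = ".")
  uk <- unique(key)
  agg <- function(m, na_rm) {
    out <- matrix(NA_real_, nrow(m), length(uk),
                  dimnames = list(rownames(m), uk))
    for (g in seq_along(uk)) {
      cols <- which(key == uk[g])
      out[, g] <- rowMeans(m[, cols, drop = FALSE], na.rm = na_rm)
    }
    out[is.nan(out)] <- NA_real_
    out
  }
  new_samples <- data.frame(sample_id = uk,
                            donor = s$donor[match(uk, key)],
                            sex = s$sex[match(uk, key)],
                            age = s$age[match(uk, key)],
                            tissue = s$region[match(uk, key)],
                            stringsAsFactors = FALSE)
  structure(list(samples = new_samples, tpm = agg(cohort$tpm, FALSE),
                 psi = agg(cohort$psi, TRUE),
                 junction_counts = agg(cohort$junction_counts, FALSE),
                 features = cohort$features, truth = cohort$truth),
            class = "tx_cohort")
}

#' Scaling normalization of a feature matrix
#'
#' Per feature, subtracts the mean across samples and divides by the average
#' absolute deviation from the mean (AveDis), so each row has mean 0 and mean
#' absolute value 1. This puts PSI and TPM features on a common scale for the
#' regression models.
#'
#' @param mat features x samples matrix with no constant rows.
#' @return an object of class `tx_norm`: list with `values`, `mean`, `avedis`.
#' @export
normalize_scaling <- function(mat) {
  mu <- rowMeans(mat)
  centered <- mat - mu
  avedis <- rowMeans(abs(centered))
  if (any(avedis == 0)) {
    bad <- rownames(mat)[avedis == 0]
    stop("constant feature row(s): ", paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) sprintf(" (+%d more)", length(bad) - 5), call. = FALSE)
  }
  structure(list(values = centered / avedis, mean = mu, avedis = avedis),
            class = "tx_norm")
}

#' Run the full preprocessing chain on a cohort stratum
#'
#' Applies, in order: sample missingness filter, gene filter, the seven splice
#' event rules, and kNN PSI imputation; then returns analysis-ready raw and
#' scaling-normalized matrices plus a combined filter report.
#'
#' @param cohort a `tx_cohort` (typically one tissue).
#' @param knn_k neighbour count for PSI imputation.
#' @return list with `samples`, `tpm`, `psi` (imputed), `norm_tpm`, `norm_psi`
#'   (`tx_norm` objects on log2(TPM+1) and PSI), `gene_map`, `report`.
#' @export
preprocess_cohort <- function(cohort, knn_k = 10) {
  fs <- filter_samples_by_missingness(cohort$psi)
  keep_s <- fs$retained
  tpm <- cohort$tpm[, keep_s, drop = FALSE]
  psi <- cohort$psi[, keep_s, drop = FALSE]
  jc <- cohort$junction_counts[, keep_s, drop = FALSE]
  fg <- filter_genes(tpm)
  tpm <- tpm[fg$retained, , drop = FALSE]
  gene_map <- stats::setNames(cohort$features$gene, cohort$features$feature_id)
  gene_map <- gene_map[rownames(psi)]
  # rule 7 consults the full gene TPM (a host gene may itself be filtered)
  fe <- filter_splice_events(psi, jc, cohort$tpm[, keep_s, drop = FALSE], gene_map)
  psi <- psi[fe$retained, , drop = FALSE]
  psi <- impute_missing_psi(psi, k = knn_k)
  samples <- cohort$samples[match(keep_s, cohort$samples$sample_id), ]
  # drop any residual constant rows before scaling
  l2 <- log2(tpm + 1)
  keep_g <- apply(l2, 1, function(x) stats::sd(x) > 0)
  keep_e <- apply(psi, 1, function(x) stats::sd(x) > 0)
  list(samples = samples, tpm = tpm[keep_g, , drop = FALSE],
       psi = psi[keep_e, , drop = FALSE],
       norm_tpm = normalize_scaling(l2[keep_g, , drop = FALSE]),
       norm_psi = normalize_scaling(psi[keep_e, , drop = FALSE]),
       gene_map = gene_map,
       report = list(samples = fs$report, genes = fg$report, events = fe$report))
}
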