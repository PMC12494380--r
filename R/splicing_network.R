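#' Correlate splicing-factor expression with event inclusion
#'
#' Spearman correlation between each splicing factor's TPM and each event's
#' PSI across the samples of one sex stratum. Pairs pass at p < 0.05. Pairs
#' with constant SF expression are skipped; strata below `min_n` samples yield
#' all pairs skipped.
#'
#' @param sf_tpm SFs x samples matrix.
#' @param event_psi events x samples matrix (columns aligned with `sf_tpm`).
#' @param min_n minimum stratum size (default 5).
#' @return data.frame: sf, event, rho, p, pass, skipped.
#' @export
correlate_sf_events <- function(sf_tpm, event_psi, min_n = 5) {
  .assert(ncol(sf_tpm) == ncol(event_psi), "matrices must share samples")
  grid <- expand.grid(sf = rownames(sf_tpm), event = rownames(event_psi),
                      stringsAsFactors = FALSE)
  n <- ncol(sf_tpm)
  if (n < min_n) {
    grid$rho <- NA_real_; grid$p <- NA_real_
    grid$pass <- FALSE; grid$skipped <- TRUE
    return(grid)
  }
  res <- mapply(function(sf, ev) {
    x <- sf_tpm[sf, ]; y <- event_psi[ev, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(c(NA_real_, NA_real_, 0))
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    c(unname(ct$estimate), ct$p.value, 1)
  }, grid$sf, grid$event)
  grid$rho <- res[1, ]
  grid$p <- res[2, ]
  grid$skipped <- res[3, ] == 0
  grid$pass <- !grid$skipped & grid$p < 0.05
  grid
}

#' Differential splicing upon splicing-factor knockdown
#'
#' Per (SF, event): OLS of replicate PSI on the arm indicator
#' (`psi ~ mu + beta_G Group`, Group coded control = 0 / shRNA = 1) with a
#' two-sided p-value for `beta_G`.
#'
#' @param kd data.frame with columns sf, event, arm (`control`/`shRNA`),
#'   replicate, psi.
#' @return data.frame of class columns: sf, event, beta_g, p, n_control,
#'   n_shrna, pass (p < 0.05).
#' @export
knockdown_differential <- function(kd) {
  .assert(all(c("sf", "event", "arm", "psi") %in% names(kd)),
          "kd table needs columns sf, event, arm, psi")
  .assert(all(kd$arm %in% c("control", "shRNA")), "arm must be control/shRNA")
  out <- list()
  for (key in unique(paste(kd$sf, kd$event, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- kd[kd$sf == parts[1] & kd$event == parts[2], ]
    nc <- sum(sub$arm == "control"); nk <- sum(sub$arm == "shRNA")
    .assert(nc >= 2 && nk >= 2, "need >= 2 replicates per arm")
    g <- as.numeric(sub$arm == "shRNA")
    fit <- stats::lm(sub$psi ~ g)
    sm <- summary(fit)$coefficients
    out[[length(out) + 1]] <- data.frame(
      sf = parts[1], event = parts[2],
      beta_g = unname(sm["g", "Estimate"]),
      p = unname(sm["g", "Pr(>|t|)"]),
      n_control = nc, n_shrna = nk, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$pass <- res$p < 0.05
  res
}

#' Motif-binding evidence from a sliding-window score profile
#'
#' The window scores (window 40 nt, step 1 nt over the +/- 300 nt splice-site
#' flanks) are rearranged into consecutive bins of `bin_width` scores
#' (an incomplete trailing bin is dropped). The bins with the highest and
#' lowest mean score are compared by a two-sided Wilcoxon rank-sum test; the
#' evidence passes iff the overall maximum score exceeds 1 AND the rank-sum
#' p-value is below 0.05.
#'
#' @param scores numeric vector of window scores (a per-event concatenation of
#'   per-site profiles, or one site's profile).
#' @param bin_width scores per bin (default 20).
#' @return list of class `tx_motif`: max_score, p, pass, bin index of the
#'   extreme bins.
#' @export
motif_binding_evidence <- function(scores, bin_width = 20) {
  n_bins <- length(scores) %/% bin_width
  .assert(n_bins >= 2, "profile shorter than two bins")
  use <- scores[seq_len(n_bins * bin_width)]
  bins <- matrix(use, nrow = bin_width)
  means <- colMeans(bins)
  hi <- which.max(means); lo <- which.min(means)
  wt <- suppressWarnings(stats::wilcox.test(bins[, hi], bins[, lo],
                                            alternative = "two.sided"))
  p <- wt$p.value
  structure(list(max_score = max(scores), p = p,
                 pass = max(scores) > 1 && p < 0.05,
                 bin_max = hi, bin_min = lo, n_bins = n_bins),
            class = "tx_motif")
}

# evaluate motif evidence for every (sf, event) in a long profile table
.motif_evidence_table <- function(profiles, bin_width = 20) {
  keys <- unique(profiles[, c("sf", "event")])
  keys$max_score <- NA_real_; keys$p_motif <- NA_real_; keys$motif_pass <- FALSE
  for (i in seq_len(nrow(keys))) {
    sc <- profiles$score[profiles$sf == keys$sf[i] &
                           profiles$event == keys$event[i]]
    ev <- motif_binding_evidence(sc, bin_width)
    keys$max_score[i] <- ev$max_score
    keys$p_motif[i] <- ev$p
    keys$motif_pass[i] <- ev$pass
  }
  keys
}

#' Build the splicing-factor regulatory network
#'
#' An edge between an age-associated splicing factor and a sex-biased
#' age-associated event exists iff all three evidence layers pass: expression-
#' inclusion correlation (p < 0.05), knockdown perturbation (p < 0.05), and a
#' localized motif-binding signal (max score > 1 and rank-sum p < 0.05).
#'
#' @param correlations output of [correlate_sf_events()].
#' @param knockdown output of [knockdown_differential()].
#' @param motif either a long profile table (columns sf, event, window, score)
#'   or a precomputed evidence table from profiles.
#' @param sf_set splicing-factor ids to consider (age-associated SFs).
#' @param event_set event ids to consider (sBASEs).
#' @param sex sex context label ("F" or "M"), recorded on the edges.
#' @return list of class `tx_network`: `edges` (one row per passing pair with
#'   all three evidence records), `candidates` (all pairs with pass flags),
#'   `summary` (edge counts per SF).
#' @export
build_network <- function(correlations, knockdown, motif, sf_set, event_set,
                          sex = "F") {
  want <- expand.grid(sf = sf_set, event = event_set, stringsAsFactors = FALSE)
  if (nrow(want) == 0) {
    edges <- data.frame(sf = character(0), event = character(0),
                        sex = character(0))
    return(structure(list(edges = edges, candidates = edges,
                          summary = data.frame(sf = character(0), n_edges = integer(0))),
                     class = "tx_network"))
  }
  if (!is.null(motif$score)) motif <- .motif_evidence_table(motif)
  key <- function(d) paste(d$sf, d$event)
  for (nm in c("correlations", "knockdown", "motif")) {
    tab <- get(nm)
    missing_pairs <- setdiff(key(want), key(tab))
    .assert(length(missing_pairs) == 0,
            paste0("pairs absent from ", nm, " evidence: ",
                   paste(utils::head(missing_pairs, 5), collapse = "; ")))
  }
  m <- match(key(want), key(correlations))
  want$rho <- correlations$rho[m]
  want$p_corr <- correlations$p[m]
  want$corr_pass <- correlations$pass[m]
  m <- match(key(want), key(knockdown))
  want$beta_g <- knockdown$beta_g[m]
  want$p_kd <- knockdown$p[m]
  want$kd_pass <- knockdown$pass[m]
  m <- match(key(want), key(motif))
  want$max_score <- motif$max_score[m]
  want$p_motif <- motif$p_motif[m]
  want$motif_pass <- motif$motif_pass[m]
  want$sex <- sex
  want$edge <- want$corr_pass & want$kd_pass & want$motif_pass
  edges <- want[want$edge, setdiff(names(want), "edge")]
  rownames(edges) <- NULL
  counts <- table(factor(edges$sf, levels = sf_set))
  structure(list(edges = edges, candidates = want,
                 summary = data.frame(sf = names(counts),
                                      n_edges = as.integer(counts),
                                      stringsAsFactors = FALSE)),
            class = "tx_network")
}
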