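#' Run the full analysis pipeline on a synthetic cohort
#'
#' Convenience driver: simulate (or accept) a cohort, preprocess, compute sex
#' and age pcSVR screens, fit the interaction and sex-stratified models with
#' surrogate variables, classify sBASEs, build the splicing-factor network from
#' simulated knockdown and motif evidence, compute per-sex aging-rate curves
#' with breakpoints, and run the AMG disturbance analysis. Reports are written
#' as TSV/JSON under `out_dir` when given.
#'
#' @param cohort a `tx_cohort` (e.g. from [generate_cohort()]).
#' @param out_dir optional output directory for reports.
#' @param seed integer seed for the stochastic stages.
#' @param pcsvr_iter iterations for the pcSVR empirical p (default 200).
#' @param n_sv surrogate-variable count (`NULL` = automatic selection).
#' @param w_range window spans for the rate curve (default 5:15).
#' @param amg_iter disturbance iterations (default 200); set 0 to skip AMG.
#' @param knn_k imputation neighbour count.
#' @return list with the per-stage results.
#' @export
run_pipeline <- function(cohort, out_dir = NULL, seed = 1L, pcsvr_iter = 200,
                         n_sv = NULL, w_range = 5:15, amg_iter = 200,
                         knn_k = 10) {
  pp <- preprocess_cohort(cohort, knn_k = knn_k)
  samples <- pp$samples

  scr_sex <- pcsvr_screen(cohort, "sex", n_iter = pcsvr_iter, seed = seed)
  scr_age <- pcsvr_screen(cohort, "age", n_iter = pcsvr_iter, seed = seed)

  svs <- estimate_surrogate_variables(pp$norm_tpm, samples, k = n_sv)
  fit_ge <- fit_interaction_model(pp$norm_tpm, samples, svs)
  calls_ge <- call_differential(fit_ge, pp$tpm, samples, "expression", "age")
  svs_as <- estimate_surrogate_variables(pp$norm_psi, samples, k = n_sv)
  fit_as <- fit_interaction_model(pp$norm_psi, samples, svs_as)
  calls_as <- call_differential(fit_as, pp$psi, samples, "splicing", "age")

  strat_as <- fit_sex_stratified_model(pp$norm_psi, pp$psi, samples,
                                       data_type = "splicing")
  sbase <- strat_as$labels[!is.na(strat_as$labels$label) &
                             strat_as$labels$label != "common", ]

  # network stage: knockdown + motif evidence simulated from planted truth
  network <- NULL
  sf_effects <- Filter(function(e) e$kind == "sf_regulation",
                       cohort$truth$effects)
  if (length(sf_effects) > 0 && nrow(sbase) > 0) {
    sf_ids <- vapply(sf_effects, function(e) e$sf, character(1))
    # candidate events: sBASEs plus the regulated events surviving the filters
    events <- union(intersect(sbase$feature, rownames(pp$psi)),
                    intersect(unlist(lapply(sf_effects, `[[`,
                                            "target_features")),
                              rownames(pp$psi)))
    targets <- lapply(sf_effects, function(e) intersect(e$target_features,
                                                        events))
    names(targets) <- sf_ids
    kd <- generate_knockdown_experiment(events, targets, seed = seed + 1)
    prof <- generate_motif_profiles(events, sf_ids,
                                    do.call(rbind, lapply(sf_ids, function(s)
                                      if (length(targets[[s]]))
                                        data.frame(sf = s, event = targets[[s]])
                                      else NULL)) %||%
                                      data.frame(sf = character(0),
                                                 event = character(0)),
                                    seed = seed + 2)
    keep_s <- samples$sex == "F"
    corr <- correlate_sf_events(pp$tpm[intersect(sf_ids, rownames(pp$tpm)), ,
                                       drop = FALSE][, keep_s, drop = FALSE],
                                pp$psi[events, keep_s, drop = FALSE])
    kdf <- knockdown_differential(kd)
    network <- build_network(corr, kdf, prof,
                             sf_set = intersect(sf_ids, rownames(pp$tpm)),
                             event_set = events, sex = "F")
  }

  # breakpoints + AMG on gene expression
  cca <- correct_confounders_and_average(pp$norm_tpm, samples, svs)
  curves <- list(); bps <- list(); chron <- list()
  for (sx in names(cca$trajectories)) {
    if (ncol(cca$trajectories[[sx]]) < 20) next
    ch <- select_chronological_features(cca$trajectories[[sx]])
    chron[[sx]] <- ch
    idx <- samples$sex == sx
    if (length(ch$selected) >= 3) {
      curves[[sx]] <- compute_rate_curve(cca$corrected[, idx, drop = FALSE],
                                         samples$age[idx], ch$selected,
                                         w_range = w_range)
      bps[[sx]] <- detect_breakpoints(curves[[sx]])
    }
  }
  sex_cmp <- if (all(c("F", "M") %in% names(curves)))
    compare_sex_rate_curves(curves$F, curves$M) else NULL

  amg <- list()
  if (amg_iter > 0) {
    for (sx in names(chron)) {
      sel <- chron[[sx]]$selected
      if (length(sel) <= 10) next
      idx <- samples$sex == sx
      rec <- disturbance_iterations(cca$corrected[, idx, drop = FALSE],
                                    samples$age[idx], sel, n_iter = amg_iter,
                                    seed = seed + 10, w_range = w_range)
      amg[[sx]] <- call_amgs(rec)
    }
  }

  res <- list(preprocess = pp$report, pcsvr_sex = scr_sex, pcsvr_age = scr_age,
              interaction_ge = fit_ge, calls_ge = calls_ge,
              interaction_as = fit_as, calls_as = calls_as,
              stratified_as = strat_as, sbase = sbase, network = network,
              rate_curves = curves, breakpoints = bps, sex_comparison = sex_cmp,
              amg = amg)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(d, f) data.table::fwrite(d, file.path(out_dir, f), sep = "\t")
    wt(rbind(scr_sex, scr_age), "pcsvr_results.tsv")
    wt(calls_ge, "calls_ge.tsv")
    wt(calls_as, "calls_as.tsv")
    if (!is.null(strat_as$labels)) wt(strat_as$labels, "stratified_as.tsv")
    if (nrow(sbase)) wt(sbase, "sbase.tsv")
    if (!is.null(network)) wt(network$edges, "edges.tsv")
    for (sx in names(curves))
      wt(data.frame(age = curves[[sx]]$ages, rate = curves[[sx]]$rate),
         sprintf("rates_%s.tsv", sx))
    for (sx in names(bps))
      if (nrow(bps[[sx]]$breakpoints))
        wt(bps[[sx]]$breakpoints, sprintf("breakpoints_%s.tsv", sx))
    for (sx in names(amg)) wt(amg[[sx]], sprintf("amg_%s.tsv", sx))
    jsonlite::write_json(pp$report, file.path(out_dir, "filter_report.json"),
                         auto_unbox = TRUE, force = TRUE)
  }
  res
}
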