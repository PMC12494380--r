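#' Configure a synthetic cohort
#'
#' Builds a validated configuration for [generate_cohort()]. The generator
#' emulates a multi-tissue human cohort with paired gene-expression (TPM) and
#' splice-event (PSI) matrices over donors aged 20-79 of both sexes, with
#' planted sex shifts, linear age slopes, age-by-sex interactions, sex-specific
#' non-linear trajectories with known breakpoint ages, latent batch factors and
#' missing PSI entries.
#'
#' @param n_donors number of donors (>= 4).
#' @param sex_ratio fraction of female donors in `[0, 1]`.
#' @param age_range integer vector `c(min, max)`, within `[20, 79]`.
#' @param tissues character vector of tissue labels; each donor contributes one
#'   sample per tissue.
#' @param n_genes,n_events numbers of genes and splice events.
#' @param effect_blocks list of [planted_effect()] descriptions.
#' @param n_latent_factors number of latent batch factors; each loads on a
#'   random 30% of features.
#' @param missing_psi_rate fraction of PSI entries set missing completely at
#'   random.
#' @param noise_sd_expr within-group SD of log2 expression noise; planted
#'   expression magnitudes are expressed in units of this SD.
#' @param noise_sd_psi SD of logit-scale PSI noise.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return an object of class `tx_cohort_config`.
#' @export
cohort_config <- function(n_donors = 100, sex_ratio = 0.5,
                          age_range = c(20, 79), tissues = "tissue1",
                          n_genes = 200, n_events = 300,
                          effect_blocks = list(), n_latent_factors = 0,
                          missing_psi_rate = 0.01,
                          noise_sd_expr = 0.5, noise_sd_psi = 0.4,
                          seed = 1L) {
  .assert(n_donors >= 4, "n_donors must be >= 4")
  .assert(sex_ratio >= 0 && sex_ratio <= 1, "sex_ratio must be in [0, 1]")
  .assert(length(age_range) == 2 && age_range[1] >= 20 && age_range[2] <= 79 &&
            age_range[1] <= age_range[2],
          "age_range must lie within [20, 79]")
  .assert(missing_psi_rate >= 0 && missing_psi_rate <= 1,
          "missing_psi_rate must be in [0, 1]")
  .assert(n_genes >= 1 && n_events >= 1, "need at least one gene and one event")
  .assert(length(tissues) >= 1, "need at least one tissue")
  for (ef in effect_blocks) {
    .assert(inherits(ef, "tx_planted_effect"),
            "effect_blocks must be a list of planted_effect() objects")
    if (ef$kind == "breakpoint_trajectory")
      .assert(ef$breakpoint_age > age_range[1] && ef$breakpoint_age < age_range[2],
              "breakpoint_age must lie inside age_range")
  }
  structure(list(n_donors = n_donors, sex_ratio = sex_ratio,
                 age_range = as.integer(age_range), tissues = tissues,
                 n_genes = n_genes, n_events = n_events,
                 effect_blocks = effect_blocks,
                 n_latent_factors = n_latent_factors,
                 missing_psi_rate = missing_psi_rate,
                 noise_sd_expr = noise_sd_expr, noise_sd_psi = noise_sd_psi,
                 seed = as.integer(seed)),
            class = "tx_cohort_config")
}

#' Describe a planted effect
#'
#' @param kind one of `"sex_shift"`, `"age_slope"`, `"interaction"`,
#'   `"breakpoint_trajectory"`, `"sf_regulation"`.
#' @param axis `"gene"` or `"event"`: which feature axis the effect targets.
#' @param n_targets number of affected features (targets are drawn at random,
#'   disjoint across effect blocks, and recorded in the cohort truth).
#' @param target_features optional explicit feature ids (overrides `n_targets`).
#' @param magnitude effect size: within-group SD units of log2 expression for
#'   gene effects, delta-PSI units for event effects. For `age_slope` and
#'   `interaction` the magnitude is per year of age; for `sex_shift` it is the
#'   male-minus-female offset; for `breakpoint_trajectory` it is the total step
#'   height across the breakpoint; for `sf_regulation` it is delta-PSI per SD
#'   of splicing-factor expression.
#' @param breakpoint_age breakpoint age in years (for `breakpoint_trajectory`).
#' @param sex_specificity `"both"`, `"female_only"` or `"male_only"`.
#' @param sf for `sf_regulation`: the regulator gene id (assigned at generation
#'   when `NULL`).
#' @return an object of class `tx_planted_effect`.
#' @export
planted_effect <- function(kind, axis = c("gene", "event"), n_targets = 10,
                           target_features = NULL, magnitude = 1,
                           breakpoint_age = NA_real_,
                           sex_specificity = c("both", "female_only", "male_only"),
                           sf = NULL) {
  kind <- match.arg(kind, c("sex_shift", "age_slope", "interaction",
                            "breakpoint_trajectory", "sf_regulation"))
  axis <- match.arg(axis)
  sex_specificity <- match.arg(sex_specificity)
  .assert(is.finite(magnitude), "magnitude must be finite")
  if (kind == "sf_regulation") axis <- "event"
  structure(list(kind = kind, axis = axis, n_targets = n_targets,
                 target_features = target_features, magnitude = magnitude,
                 breakpoint_age = breakpoint_age,
                 sex_specificity = sex_specificity, sf = sf),
            class = "tx_planted_effect")
}

# per-sample multiplier restricting an effect to one sex
.sex_mask <- function(spec, sex01) {
  switch(spec,
         both = rep(1, length(sex01)),
         female_only = as.numeric(sex01 == 0),
         male_only = as.numeric(sex01 == 1))
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Expression effects are realized additively on the log2-TPM scale in units of
#' the within-group noise SD; splicing effects are realized additively on the
#' logit-PSI scale, scaled by the local derivative `1 / (p0 (1 - p0))` so that
#' magnitudes are honored in delta-PSI units near the event baseline, then
#' back-transformed. Latent batch factors load linearly on a random 30% of
#' genes and events. Missing PSI entries are assigned completely at random.
#'
#' @param config a [cohort_config()] object.
#' @return an object of class `tx_cohort`: a list with `samples` (data.frame
#'   with sample_id, donor, sex, age, tissue), `tpm`, `psi`, `junction_counts`
#'   (features x samples matrices), `features` (annotation data.frame) and
#'   `truth` (realized effects, latent factors).
#' @export
generate_cohort <- function(config) {
  .assert(inherits(config, "tx_cohort_config"), "config must be a cohort_config()")
  set.seed(config$seed)
  nd <- config$n_donors
  n_f <- round(nd * config$sex_ratio)
  sex <- sample(rep(c("F", "M"), times = c(n_f, nd - n_f)))
  age <- sample(seq(config$age_range[1], config$age_range[2]), nd, replace = TRUE)
  donors <- sprintf("D%04d", seq_len(nd))
  samples <- expand.grid(donor = donors, tissue = config$tissues,
                         stringsAsFactors = FALSE)
  samples$sex <- sex[match(samples$donor, donors)]
  samples$age <- age[match(samples$donor, donors)]
  samples$sample_id <- paste(samples$donor, samples$tissue, sep = ".")
  samples <- samples[, c("sample_id", "donor", "sex", "age", "tissue")]
  ns <- nrow(samples)
  sex01 <- .sex01(samples$sex)
  age_mid <- mean(config$age_range)

  gene_ids <- sprintf("g%04d", seq_len(config$n_genes))
  event_ids <- sprintf("e%04d", seq_len(config$n_events))
  chrom <- sample(c(paste0("chr", 1:22), "chrX", "chrY"), config$n_genes,
                  replace = TRUE, prob = c(rep(0.92 / 22, 22), 0.06, 0.02))
  host <- sample(gene_ids, config$n_events, replace = TRUE)
  ev_type <- sample(c("SE", "A5SS", "A3SS", "RI"), config$n_events,
                    replace = TRUE, prob = c(0.55, 0.15, 0.15, 0.15))
  ev_start <- sample.int(2e6, config$n_events)
  features <- rbind(
    data.frame(feature_id = gene_ids, kind = "gene", gene = gene_ids,
               chromosome = chrom, event_type = NA_character_,
               start = NA_integer_, end = NA_integer_,
               stringsAsFactors = FALSE),
    data.frame(feature_id = event_ids, kind = "event", gene = host,
               chromosome = chrom[match(host, gene_ids)], event_type = ev_type,
               start = ev_start, end = ev_start + sample(50:5000, config$n_events,
                                                         replace = TRUE),
               stringsAsFactors = FALSE))

  # assign effect targets, disjoint per axis across blocks
  effects <- config$effect_blocks
  free <- list(gene = gene_ids, event = event_ids)
  for (i in seq_along(effects)) {
    ef <- effects[[i]]
    if (is.null(ef$target_features)) {
      .assert(length(free[[ef$axis]]) >= ef$n_targets,
              "not enough free features to place planted effects")
      tgt <- sample(free[[ef$axis]], ef$n_targets)
      effects[[i]]$target_features <- tgt
    } else {
      tgt <- ef$target_features
      .assert(all(tgt %in% c(gene_ids, event_ids)), "unknown target feature id")
    }
    free[[ef$axis]] <- setdiff(free[[ef$axis]], tgt)
    if (ef$kind == "sf_regulation" && is.null(effects[[i]]$sf)) {
      effects[[i]]$sf <- sample(free$gene, 1)
      free$gene <- setdiff(free$gene, effects[[i]]$sf)
    }
  }

  # per-sample design value of each effect kind (unit scale)
  design_value <- function(ef) {
    msk <- .sex_mask(ef$sex_specificity, sex01)
    switch(ef$kind,
           sex_shift = sex01,
           age_slope = (samples$age - age_mid) * msk,
           interaction = sex01 * (samples$age - age_mid),
           breakpoint_trajectory = stats::plogis(samples$age - ef$breakpoint_age) * msk,
           sf_regulation = NULL)
  }

  # expression: baseline + effects + latent + noise, on log2 scale
  base_g <- stats::rnorm(config$n_genes, mean = 3, sd = 1.5)
  log2tpm <- matrix(base_g, config$n_genes, ns) +
    matrix(stats::rnorm(config$n_genes * ns, sd = config$noise_sd_expr),
           config$n_genes, ns)
  dimnames(log2tpm) <- list(gene_ids, samples$sample_id)
  for (ef in effects) {
    if (ef$axis != "gene" || ef$kind == "sf_regulation") next
    dv <- design_value(ef)
    idx <- match(ef$target_features, gene_ids)
    log2tpm[idx, ] <- log2tpm[idx, ] +
      ef$magnitude * config$noise_sd_expr * matrix(dv, length(idx), ns, byrow = TRUE)
  }

  # splicing: baseline + effects on logit scale (delta-PSI calibrated)
  event_targets <- unlist(lapply(effects,
                                 function(ef) if (ef$axis == "event") ef$target_features))
  base_p <- stats::plogis(stats::rnorm(config$n_events, 0, 1.2))
  base_p[match(event_targets, event_ids)] <-
    stats::runif(length(event_targets), 0.25, 0.75)
  logit_psi <- matrix(stats::qlogis(base_p), config$n_events, ns)
  dimnames(logit_psi) <- list(event_ids, samples$sample_id)
  dpsi_scale <- 1 / (base_p * (1 - base_p))  # local logit derivative
  for (ef in effects) {
    if (ef$axis != "event" || ef$kind == "sf_regulation") next
    dv <- design_value(ef)
    idx <- match(ef$target_features, event_ids)
    logit_psi[idx, ] <- logit_psi[idx, ] +
      ef$magnitude * dpsi_scale[idx] * matrix(dv, length(idx), ns, byrow = TRUE)
  }
  # SF -> event regulation: event mean tracks the regulator's expression
  for (ef in effects) {
    if (ef$kind != "sf_regulation") next
    sf_expr <- log2tpm[ef$sf, ]
    z <- as.numeric(scale(sf_expr))
    idx <- match(ef$target_features, event_ids)
    logit_psi[idx, ] <- logit_psi[idx, ] +
      ef$magnitude * dpsi_scale[idx] * matrix(z, length(idx), ns, byrow = TRUE)
  }

  # latent batch factors on a random 30% of each feature axis
  latent <- NULL
  if (config$n_latent_factors > 0) {
    latent <- matrix(stats::rnorm(ns * config$n_latent_factors), ns)
    colnames(latent) <- sprintf("latent%d", seq_len(config$n_latent_factors))
    for (k in seq_len(config$n_latent_factors)) {
      gsub_idx <- sample(config$n_genes, round(0.3 * config$n_genes))
      esub_idx <- sample(config$n_events, round(0.3 * config$n_events))
      gl <- stats::rnorm(length(gsub_idx), sd = 0.8) * config$noise_sd_expr
      el <- stats::rnorm(length(esub_idx), sd = 0.8)
      log2tpm[gsub_idx, ] <- log2tpm[gsub_idx, ] + outer(gl, latent[, k])
      logit_psi[esub_idx, ] <- logit_psi[esub_idx, ] + outer(el, latent[, k])
    }
  }

  logit_psi <- logit_psi +
    matrix(stats::rnorm(config$n_events * ns, sd = config$noise_sd_psi),
           config$n_events, ns)
  psi <- stats::plogis(logit_psi)
  tpm <- 2^log2tpm

  # junction counts supporting each event's quantification
  jc_mean <- exp(stats::rnorm(config$n_events, log(60), 0.6))
  junction_counts <- matrix(stats::rpois(config$n_events * ns,
                                         rep(jc_mean, ns)),
                            config$n_events, ns,
                            dimnames = list(event_ids, samples$sample_id))

  if (config$missing_psi_rate > 0) {
    miss <- stats::runif(length(psi)) < config$missing_psi_rate
    psi[miss] <- NA_real_
  }

  structure(list(samples = samples, tpm = tpm, psi = psi,
                 junction_counts = junction_counts, features = features,
                 truth = list(effects = effects, latent_factors = latent,
                              config = config)),
            class = "tx_cohort")
}

#' @export
print.tx_cohort <- function(x, ...) {
  cat(sprintf("tx_cohort: %d samples (%d donors, %d tissues), %d genes, %d events\n",
              nrow(x$samples), length(unique(x$samples$donor)),
              length(unique(x$samples$tissue)), nrow(x$tpm), nrow(x$psi)))
  cat(sprintf("  planted effects: %d; missing PSI: %.2f%%\n",
              length(x$truth$effects), 100 * mean(is.na(x$psi))))
  invisible(x)
}

#' Simulate a splicing-factor knockdown experiment
#'
#' Emulates control vs shRNA PSI tables: events targeted by a knocked-down
#' regulator shift by `effect` delta-PSI in the shRNA arm; all other events are
#' unchanged up to replicate noise.
#'
#' @param events character vector of event ids measured in the experiment.
#' @param sf_targets named list mapping each knocked-down splicing-factor id to
#'   the event ids it regulates (may be empty vectors).
#' @param n_reps replicates per arm (>= 2).
#' @param effect delta-PSI applied to targeted events in the shRNA arm.
#' @param noise_sd replicate noise SD on the PSI scale.
#' @param baseline optional named numeric of baseline PSI per event; defaults
#'   to draws in `[0.3, 0.7]`.
#' @param seed integer seed.
#' @return data.frame with columns sf, event, arm (`control`/`shRNA`),
#'   replicate, psi.
#' @export
generate_knockdown_experiment <- function(events, sf_targets, n_reps = 4,
                                          effect = 0.3, noise_sd = 0.01,
                                          baseline = NULL, seed = 1L) {
  .assert(n_reps >= 2, "n_reps must be >= 2 (no residual degrees of freedom otherwise)")
  .assert(length(events) >= 1, "need at least one event")
  bad <- setdiff(unlist(sf_targets), events)
  .assert(length(bad) == 0,
          paste("unknown target event id(s):", paste(bad, collapse = ", ")))
  set.seed(seed)
  if (is.null(baseline)) {
    baseline <- stats::runif(length(events), 0.3, 0.7)
    names(baseline) <- events
  }
  out <- list()
  for (sf in names(sf_targets)) {
    for (arm in c("control", "shRNA")) {
      shift <- ifelse(arm == "shRNA" & events %in% sf_targets[[sf]], effect, 0)
      for (r in seq_len(n_reps)) {
        out[[length(out) + 1]] <- data.frame(
          sf = sf, event = events, arm = arm, replicate = r,
          psi = .clamp(baseline[events] + shift +
                         stats::rnorm(length(events), sd = noise_sd), 0, 1),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate per-window motif-binding score profiles
#'
#' Produces sliding-window binding-score profiles over the +/- `region_half_width`
#' nt flank of an event's alternative splice sites (window 40 nt, step 1 nt).
#' Planted regulator-event pairs receive one contiguous elevated segment with
#' maximum score above 1; all other pairs receive flat low-score noise with
#' maximum below 1.
#'
#' @param events,regulators id vectors (namespaces must not overlap).
#' @param planted_pairs data.frame with columns `sf`, `event` (may have 0 rows).
#' @param region_half_width flank half-width in nt (default 300).
#' @param window,step window geometry in nt.
#' @param seed integer seed.
#' @return data.frame with columns sf, event, window (1-based index), score.
#' @export
generate_motif_profiles <- function(events, regulators, planted_pairs,
                                    region_half_width = 300, window = 40,
                                    step = 1, seed = 1L) {
  .assert(length(intersect(events, regulators)) == 0,
          "event and regulator id namespaces overlap")
  .assert(region_half_width >= 20,
          "region_half_width must cover at least one score bin")
  set.seed(seed)
  n_win <- (2 * region_half_width - window) %/% step + 1
  planted_key <- character(0)
  if (nrow(planted_pairs) > 0)
    planted_key <- paste(planted_pairs$sf, planted_pairs$event)
  grid <- expand.grid(sf = regulators, event = events, stringsAsFactors = FALSE)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    prof <- stats::runif(n_win, 0.05, 0.4)
    if (paste(grid$sf[i], grid$event[i]) %in% planted_key) {
      seg_len <- 40
      s0 <- sample.int(n_win - seg_len + 1, 1)
      prof[s0:(s0 + seg_len - 1)] <- stats::runif(seg_len, 1.5, 2.5)
    }
    out[[i]] <- data.frame(sf = grid$sf[i], event = grid$event[i],
                           window = seq_len(n_win), score = prof,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write a cohort to a tab-delimited bundle
#'
#' Writes `tpm.tsv`, `psi.tsv`, `junction_counts.tsv` (features x samples with a
#' header row of sample ids), `samples.tsv`, `features.tsv` and `truth.json`.
#'
#' @param cohort a `tx_cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wm <- function(m, f) {
    dt <- data.table::as.data.table(m, keep.rownames = "feature_id")
    data.table::fwrite(dt, file.path(dir, f), sep = "\t")
  }
  wm(cohort$tpm, "tpm.tsv")
  wm(cohort$psi, "psi.tsv")
  wm(cohort$junction_counts, "junction_counts.tsv")
  data.table::fwrite(cohort$samples, file.path(dir, "samples.tsv"), sep = "\t")
  data.table::fwrite(cohort$features, file.path(dir, "features.tsv"), sep = "\t")
  truth <- lapply(cohort$truth$effects, function(ef) unclass(ef))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(dir)
}

#' Read a cohort bundle written by [write_cohort()]
#'
#' @param dir directory containing the bundle.
#' @return a `tx_cohort` (without latent-factor truth, which is not serialized).
#' @export
read_cohort <- function(dir) {
  rm_ <- function(f) {
    dt <- data.table::fread(file.path(dir, f), sep = "\t")
    m <- as.matrix(dt[, -1])
    rownames(m) <- dt[[1]]
    m
  }
  truth_file <- file.path(dir, "truth.json")
  effects <- if (file.exists(truth_file))
    jsonlite::read_json(truth_file, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  else list()
  structure(list(samples = as.data.frame(data.table::fread(file.path(dir, "samples.tsv"))),
                 tpm = rm_("tpm.tsv"), psi = rm_("psi.tsv"),
                 junction_counts = rm_("junction_counts.tsv"),
                 features = as.data.frame(data.table::fread(file.path(dir, "features.tsv"))),
                 truth = list(effects = effects)),
            class = "tx_cohort")
}
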