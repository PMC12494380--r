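---
title: "Quantifying sex-dimorphic transcriptome aging with txaging"
author: "txaging authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sex-dimorphic transcriptome aging with txaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(txaging)
```

## The scientific problem

Human tissues change their transcriptomes with age, and they do so
differently in females and males: gene-expression (GE) programs drift at
different paces, and alternative-splicing (AS) profiles — summarized per
event as percent-spliced-in (PSI) — diverge between the sexes during aging.
`txaging` implements a pipeline for dissecting these effects in cohorts with
paired TPM (genes x samples) and PSI (events x samples) matrices plus donor
metadata (sex, age, tissue):

1. a **global variation statistic** (pcSVR) asking how much sex or age
   separates samples relative to within-group dispersion;
2. **per-feature linear models** with age-by-sex interaction terms and
   surrogate-variable (SV) adjustment, with permutation-based FDR;
3. **sex-stratified age models** classifying features as female-specific,
   male-specific, or common — sex-biased age-associated splice events
   ("sBASEs") are events significant in exactly one sex;
4. a **splicing-factor (SF) regulatory network** built from three independent
   evidence layers (expression-PSI correlation, knockdown response, localized
   motif-binding scores);
5. an **aging-rate curve** per sex from sliding-window MANOVA over ARIMA-
   filtered "chronological" features, with breakpoint detection;
6. a **disturbance analysis** flagging aging-modulated genes (AMGs) whose
   removal perturbs the aging-rate pattern.

Every stage is exercised on synthetic cohorts with planted ground truth, so
recovery can be measured rather than assumed.

## The pcSVR statistic

For two groups $X, Y$ embedded in the space of the leading principal
components (the smallest prefix capturing more than 80% of global variance;
other cutoffs are supported),

$$\mathrm{pcSVR}(X,Y) = \frac{\lVert \bar X - \bar Y \rVert_2}
  {\sqrt{\sigma_X^2 / N_x + \sigma_Y^2 / N_y}},\qquad
  \sigma_X^2 = \frac{\sum_i \lVert x_i - \bar X\rVert_2^2}{N_x - 1}.$$

Values well above 1 indicate between-group differences exceeding within-group
dispersion. PCA is centered-only: inputs arrive scaling-normalized (below), so
a further variance rescaling would distort feature weights.

The empirical p-value follows a subsampling scheme: the observed statistic is
the *mean* pcSVR over `n_iter` labeled subsamples of size
$s = \lfloor 0.5\,\min(N_x,N_y)\rfloor$ per group; the null consists of
`n_iter` label-free draws of $2s$ samples split randomly into two
pseudo-groups (the split rule is our choice; the bootstrap-with-replacement
alternative is available). PCA is refit on every draw so the observed and null
statistics face identical estimation noise. The p-value is the fraction of
null draws strictly above the observed mean; zero is reported as 0 with
resolution `1/n_iter`.

One property of this construction deserves emphasis: because the observed
statistic is an average over many subsamples while the null values are single
draws from (under exchangeability) the same distribution, the null
distribution of the p-value is **not uniform** — it concentrates near
$P(T > \mathbb{E}T) \approx 0.5$. The test is therefore *valid but
conservative*: in simulation, fewer than 2% of exchangeable-group replicates
fall below the 0.1 cutoff. Users should read the empirical p as a yes/no
screen at the chosen cutoff, not as a uniformly calibrated tail probability.
The test suite asserts the conservative validity, which is the property that
actually holds.

## Preprocessing

Filters follow fixed rules with all inequalities strict as stated: genes with
average TPM below 1 are removed; samples missing PSI in more than 50% of
events are removed; events must pass seven rules (missingness below 5%, mean
junction counts above 10, non-constant PSI, range above 0.05, SD above 0.01,
mean PSI within [0.05, 0.95], host-gene TPM above 1), and the report names the
first failing rule per removed event. The order — samples, then genes, then
events, then imputation — is a design choice: sample removal changes event
statistics, so it must come first.

Missing PSI entries are imputed by k-nearest neighbours over samples
(default k = 10, Euclidean distance over jointly observed events, unweighted
mean, clamped to [0, 1]); observed entries are never altered. Brain-region
merging averages a donor's member-region TPM/PSI values per functional region
(arithmetic mean — the operation acts on published summaries, not reads).

The scaling normalization puts PSI and TPM on a common footing per feature:

$$\mathrm{norm}(Y_{ij}) = \frac{Y_{ij} - \overline{Y_i}}{\mathrm{AveDis}(Y_i)},
 \qquad \mathrm{AveDis}(Y_i) = \frac{1}{n}\sum_j |Y_{ij} - \overline{Y_i}|,$$

so every row has mean 0 and mean absolute value 1. Constant rows are an error
by construction (upstream filters remove them).

## Differential models

Per feature, ordinary least squares of the normalized value on sex (F = 0,
M = 1), age in years, their interaction, and SVs; the interaction coefficient
deviating from 0 flags an age-by-sex interaction. SVs come from surrogate
variable analysis (two-pass residual decomposition; the count is chosen by a
permutation eigenvalue test unless supplied), and diagnostics report each SV's
correlation with known covariates (point-biserial for binary covariates,
Spearman otherwise) so confounder capture can be audited.

Differential calls combine a coefficient p-value below 0.05 with an effect
gate computed on the raw scale: fold change of group-mean TPM above 1.5
(direction-symmetric, young = age < 40 vs old = age > 60; a zero group mean
triggers a configurable pseudocount, flagged) or |delta PSI| above 0.05.
Permutation FDR shuffles sex and age jointly (one donor-label permutation)
and reuses the same thresholds inside each of the (default 1,000)
permutations; SVs are held fixed because the data, and hence its latent
structure, are unchanged by label shuffling. P-values are not otherwise
multiplicity-adjusted: the fixed p < 0.05 plus effect gates plus permutation
FDR audit is the decision rule.

Sex-stratified fits repeat the age model within each sex (minimum 10 samples
per stratum) with per-sex SVs; features significant in exactly one sex are
sex-biased, in both sexes common. Between-sex overlaps are tested
hypergeometrically and effect agreement by Spearman correlation of
$\beta_F$ vs $\beta_M$; two correlations are compared by Fisher's z.

## Regulatory network

An SF-event edge requires all three of: Spearman correlation between SF TPM
and event PSI at p < 0.05 (at least 5 samples, constant SFs skipped);
knockdown response — OLS of replicate PSI on the control/shRNA indicator with
p < 0.05 (at least 2 replicates per arm); and motif evidence — sliding-window
binding scores (window 40 nt, step 1 nt over the +/- 300 nt splice-site
flanks) rearranged into bins of 20 consecutive *scores* (the test needs
multiple observations per bin, and window scores are the stated unit), the
extreme bins compared by a two-sided rank-sum test, passing iff the overall
maximum score exceeds 1 and p < 0.05. The max-score rule is applied per event
over the concatenated site profiles; per-site application is available. The
edge set is exactly the intersection of the three single-evidence pass sets.

## Aging-rate curves and breakpoints

Trajectories are built by removing SV contributions (protecting sex, age and
their interaction) and averaging samples sharing (sex, age in years).
Features with genuine chronological structure are selected by ARIMA model
selection in the Hyndman–Khandakar style: the differencing order d is chosen
first by successive KPSS level-stationarity tests at the 5% level, then
(p, q) by minimum AIC over a bounded grid (0–2 each); a feature is kept when
d >= 1 and the fitted AR and MA coefficients are not all zero. We select d by
KPSS rather than comparing AIC across d because likelihoods at different
differencing orders are not comparable; with a pure AIC grid, white-noise
trajectories are falsely retained about 15% of the time, versus about 5-10%
with KPSS (and integrated AR(1) series are still retained in 18-20 of 20
seeds).

The rate of change at age $i$ for window span $w \in \{5,\dots,15\}$ years
compares samples aged in $(i-w, i]$ with $(i, i+w]$ (half-open bins avoid
double counting) by a two-group MANOVA (Pillai trace) on the top-3 PC scores
of the chronological submatrix; the PCA is fit once per stratum so per-age
statistics share a basis. For two groups the Pillai test is computed via its
exact Hotelling $T^2$/F equivalence (verified against `stats::manova` in the
tests) — the disturbance analysis evaluates hundreds of thousands of these.
Per span, the $-\log_{10} p$ series is LOESS-smoothed (degree 1) at each
bandwidth in 0.25–0.75 (step 0.05), averaged, smoothed once more at bandwidth
0.5, and the final curve is the mean across spans, floored at 0. LOESS spans
are floored so the local neighbourhood always holds at least 5 points, and no
extrapolation is performed.

Breakpoints: the global maximum of the curve (interior points only, earliest
age on ties) is always reported; an additional local maximum qualifies iff its
height above the nearest local minimum exceeds 10% of the global maximum.
Endpoints can serve as minima but never as breakpoints. Female and male curves
are compared by a Wilcoxon signed-rank test on the shared age grid; when all
non-zero paired differences share one sign the exact extreme-tail p-value
$2^{1-n}$ is used (tied magnitudes otherwise force a normal approximation that
understates the evidence). Identical curves are reported as "no difference"
rather than an error.

## AMG disturbance analysis

200 random trims of 20% (floor, minimum 1) of the chronological set each
recompute the rate curve; a per-gene Fisher exact test (one-sided, enrichment
of removal among significant iterations) flags AMGs at p < 0.05, over sets
larger than 10 genes.

The per-iteration significance test needs care. Removing features *always*
shrinks the rate statistic globally — fewer features average away less noise
in the PC scores — and the before/after curves share all sampling noise, so a
paired signed-rank on curve levels flags essentially every trim (~199/200 in
our simulations), destroying the contrast the Fisher test needs. The smoothed
curves are also too strongly autocorrelated for a rank test's independence
assumption. We therefore pair the *raw* per-(window, age) $-\log_{10} p$
values with each set normalized to its mean: the comparison is then
insensitive to the inevitable global shrinkage and responds to changes in the
temporal *pattern* — a collapsing or shifting peak — which is what
"perturbing the aging rate" means scientifically.

A structural limitation follows from the statistic itself: genes carrying a
shared trajectory are statistically redundant in a 3-PC population statistic,
so in large chronological sets (~50 genes) no single gene is pivotal and
per-gene enrichment has little power regardless of effect size — we measured
recall of 0–0.3 for planted genes across a wide range of designs at that set
size. Near the procedure's minimum set size (just above 10 genes), individual
genes carry substantial weight and planted pivotal genes are recovered with
recall 1.0 at a ~5% false-call rate in our tests. AMG results should
therefore be interpreted with the chronological-set size in mind.

Expression patterns of AMGs are classified over nine 5-year age windows
(20–25, 26–30, …, 61–65) of the ARIMA-fitted levels: "up at young" iff the
31–40 mean strictly exceeds the 20–30 mean; "monotone decline" iff window
means are non-increasing.

## The synthetic-data generator

`generate_cohort()` emulates a multi-tissue cohort over donors aged 20–79:
log-normal expression around gene-specific baselines (noise SD 0.5 on the
log2 scale; planted expression magnitudes are in units of this SD) and
logit-normal PSI (noise SD 0.4 on the logit scale). Splicing effect
magnitudes are in delta-PSI units, realized additively on the logit scale via
the local derivative $1/(p_0(1-p_0))$ so they are honored near the event
baseline. Effect kinds mirror the model terms: sex shifts, per-year age
slopes (optionally one sex only), age-by-sex interactions, logistic-step
breakpoint trajectories with known breakpoint age, and SF-to-event regulation
(event PSI tracks the regulator's expression). Latent batch factors load on a
random 30% of features; PSI missingness is completely at random (the real
mechanism in public cohorts is unstated, so MCAR is the neutral default,
exposed in the config); ages are uniform over the range. Junction counts are
Poisson around event-specific means (~60) so the JC filter is realistic.

What the generator does *not* emulate: read-level sampling noise and its
mean-variance structure, correlated gene programs, cell-type composition
shifts, realistic missingness-by-coverage, or genuine motif biology (motif
profiles are constructed signals: planted pairs get one contiguous elevated
segment with max score above 1, decoys flat noise below 1). Passing tests
demonstrate that the *procedures* recover what they are defined to recover,
not that real tissues satisfy the models.

Default study conditions in the test suite (chosen once as realistic for
GTEx-scale tissue cohorts): 150–300 donors per stratum, sex-shift magnitudes
around 2 SD, age slopes of 0.004 delta-PSI per year (~0.24 over the adult
range), breakpoint steps of 3–6 SD, SF-regulation coupling of 0.15 delta-PSI
per SD of SF expression, knockdown shifts of 0.3 PSI with replicate noise SD
0.01. Simulation sizes in tests (e.g., 100-gene cohorts, reduced window
grids of 5–8 years, 100–1,000 permutation iterations) are deliberate
trade-offs to keep the suite fast while leaving each check well-powered.

## Degenerate inputs and numerical conventions

Strict inequalities exactly as stated throughout the filters; subsample sizes
and trim counts use floor; "higher than" in the empirical p is strict. Zero
within-group dispersion in both pcSVR groups is an error; a zero in one group
is tolerated. Noiseless features (zero residual variance) get p = 0 for
non-zero coefficients and p = 1 otherwise, so exact constructions behave as
expected. Constant SF expression skips the pair; constant trajectories are
excluded from the chronological set without error; flat rate curves yield no
breakpoints with a warning. SV columns collinear with the design are dropped
with a warning naming them.

## Limitations

- The pcSVR empirical p is conservative by construction (see above).
- ARIMA order selection on short per-age trajectories (40–60 points) is
  noisy; the KPSS + AIC scheme controls false inclusion to roughly its
  nominal level but individual selections vary across seeds.
- AMG discovery is only powered for small chronological sets; at large sets
  the procedure's per-gene influence vanishes by construction.
- The permutation FDR treats donors as exchangeable; family structure or
  repeated measures would require a grouped permutation scheme.
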