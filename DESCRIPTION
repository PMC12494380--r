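Package: txaging
Title: Sex-Dimorphic Transcriptome Aging Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how sex and age drive gene-expression (TPM) and
    alternative-splicing (PSI) variation in human cohorts. Implements the
    principal-component-based signal-to-variation ratio (pcSVR) with
    subsampling and bootstrap permutation nulls, surrogate-variable-adjusted
    interaction and sex-stratified linear models with permutation FDR,
    sex-biased age-associated splice-event (sBASE) classification,
    splicing-factor regulatory-network inference from correlation, knockdown
    and motif-binding evidence, ARIMA-filtered sliding-window MANOVA aging-rate
    curves with breakpoint detection, and the disturbance procedure for
    aging-modulated genes (AMGs). Ships a synthetic-cohort generator with
    planted ground truth so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    limma,
    sva
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
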