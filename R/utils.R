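# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# clamp to [lo, hi]
.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# accepts either a plain numeric matrix or a NormalizedMatrix object
.as_values <- function(x) {
  if (inherits(x, "tx_norm")) x$values else as.matrix(x)
}

# sex is coded F = 0, M = 1 throughout
.sex01 <- function(sex) {
  .assert(all(sex %in% c("F", "M")), "sex must be coded 'F'/'M'")
  as.numeric(sex == "M")
}

# young/old grouping used for age contrasts: young < 40, old > 60, middle excluded
.age_group <- function(age, young_max = 40, old_min = 60) {
  g <- rep(NA_character_, length(age))
  g[age < young_max] <- "young"
  g[age > old_min] <- "old"
  g
}
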