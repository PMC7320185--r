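# Internal helpers shared across modules.

# Attach a named drop-count log to a tibble without disturbing its data.
set_drop_log <- function(x, log) {
  attr(x, "drop_log") <- log
  x
}

#' Retrieve the validation/drop log attached to a cadprio table
#'
#' Readers and harmonization steps drop rows that fail validation and record
#' how many were dropped and why. The log travels as an attribute so the data
#' itself stays a plain tibble.
#'
#' @param x A tibble returned by [read_sumstats()], [harmonize_sumstats()] or
#'   similar.
#' @return A named integer vector of drop counts (possibly empty).
#' @export
drop_log <- function(x) {
  log <- attr(x, "drop_log")
  if (is.null(log)) integer(0) else log
}

# Two-sided normal p from a z score, clamped away from exact 0.
p_from_z <- function(z) {
  pmax(2 * pnorm(-abs(z)), 1e-300)
}

# Deterministic half-up rounding to one decimal, for kb report values
# (base round() is half-to-even, which would print 269.4 as expected here but
# is not stable across all inputs).
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

# Coerce a chromosome label to a plain comparable string.
chrom_chr <- function(x) as.character(x)
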