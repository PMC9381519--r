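#' Round half away from zero
#'
#' Reporting convention used throughout: percentages are carried at full
#' precision internally and rounded only for display, with ties going away
#' from zero (so 0.25 -> 0.3 at one decimal), unlike base R's banker's
#' rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  # add a tiny relative eps so values stored as 2.4999999... from decimal
  # representation still round up; magnitudes here are percentages/ratios
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

#' Percentage of a count pair, at reporting precision
#'
#' `percent_of(46, 129)` is 35.7, the display form of 46/129 used in
#' per-SLA summary tables.
#'
#' @param num numerator count.
#' @param den denominator count (must be > 0).
#' @param digits decimal places (default 1).
#' @return numeric percentage rounded half-away-from-zero.
#' @export
percent_of <- function(num, den, digits = 1) {
  stopifnot(is.numeric(num), is.numeric(den))
  if (any(den <= 0)) stop("percent_of(): denominator must be positive")
  round_half_up(100 * num / den, digits)
}

#' Ratio of two counts at reporting precision
#'
#' e.g. mice per injected sample: `ratio_of(446, 70)` is 6.4.
#'
#' @inheritParams percent_of
#' @return numeric ratio rounded half-away-from-zero.
#' @export
ratio_of <- function(num, den, digits = 1) {
  if (any(den <= 0)) stop("ratio_of(): denominator must be positive")
  round_half_up(num / den, digits)
}

# internal: stop() with a classed condition so callers can test error classes
slaml_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "slaml_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# internal: check scalar probability
is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x <= 1)
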