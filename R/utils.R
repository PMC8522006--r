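# Internal helpers shared across modules.

# Classed errors so callers can distinguish validation problems from bugs.
stop_earsleep <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "earsleep_error", "error", "condition")))
}

#' Round half away from zero
#'
#' Rounding convention used when comparing computed statistics with
#' values printed to a fixed number of decimals (R's `round()` rounds
#' half to even, which disagrees with how tabulated values are usually
#' produced).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
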