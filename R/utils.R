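#' Round half away from zero
#'
#' Rounds to a fixed number of decimal places with ties going away from
#' zero (`0.005 -> 0.01`), the convention of printed food-composition
#' tables, rather than the IEC 60559 round-half-even rule used by
#' [base::round()]. A tiny epsilon absorbs binary representation error so
#' that values intended to sit exactly on a tie (e.g. `0.015`) round up.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector of the same length.
#' @examples
#' round_half_up(c(0.005, 0.015, 0.025), 2) # 0.01 0.02 0.03
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  y <- x * p
  sign(y) * floor(abs(y) + 0.5 + 1e-9) / p
}

# Integer "cents" of a 2-decimal display value; avoids == on doubles.
display_cents <- function(display) {
  as.integer(round(display * 100))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name, lower, upper, x))
  }
  invisible(x)
}
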