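#' Round half-up (half away from zero)
#'
#' Commercial rounding used for all displayed currency amounts and
#' percentages: halves round away from zero, so `round_half_up(0.5)` is 1 and
#' `round_half_up(-0.5)` is -1. This differs from base [round()], which rounds
#' halves to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places to keep (default 0).
#' @return Numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(11031.4167)   # 11031
#' round_half_up(2647.54)      # 2648
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1)
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# All currency arithmetic runs in integer euro cents; euros appear only at
# the interface. Cents are held in doubles (exact up to 2^53, far beyond any
# cohort total here).
as_cents <- function(euros) {
  cents <- euros * 100
  if (any(abs(cents - round(cents)) > 1e-6)) {
    stop("currency amount has sub-cent precision: ", paste(euros, collapse = ", "))
  }
  round(cents)
}

as_euros <- function(cents) cents / 100

#' Format an amount in euros
#'
#' @param x Amount in euros.
#' @param digits Decimal places to display.
#' @return Character vector like `"EUR 14,139"`.
#' @export
format_eur <- function(x, digits = 0) {
  paste0("EUR ", formatC(round_half_up(x, digits), format = "f",
                         digits = digits, big.mark = ","))
}
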