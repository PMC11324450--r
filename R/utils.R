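# Internal validation and rounding helpers.

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(name, " must be a finite numeric scalar", call. = FALSE)
  if (x < lower || (open_lower && x == lower) || x > upper)
    stop(sprintf("%s = %g is outside [%s%g, %g]", name, x,
                 if (open_lower) "open " else "", lower, upper), call. = FALSE)
  invisible(x)
}

check_frequencies <- function(frequency) {
  if (!is.numeric(frequency) || length(frequency) < 1 ||
      any(!is.finite(frequency)) || any(frequency <= 0))
    stop("frequencies must be finite and > 0", call. = FALSE)
  invisible(frequency)
}

#' Round half away from zero
#'
#' Rounding used at reporting boundaries for parity with printed tables
#' (base `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# lognormal multiplicative noise with unit mean and coefficient of variation cv
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}
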