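# Time-domain prediction from frequency-domain fits: step-strain relaxation,
# comparison against measured traces, and extrapolation of the storage
# modulus to frequencies outside the measured band.

#' Stress-relaxation trace container
#'
#' Relaxation modulus (measured shear stress divided by the step-strain
#' amplitude) versus time after a step shear strain.
#'
#' @param times Seconds after the step, positive and increasing (the organ
#'   study sampled every 1 s for 10 s).
#' @param relaxation_modulus kPa at each time.
#' @param strain_step Step amplitude, dimensionless (0.001 = 0.1%).
#' @return An object of class `relaxation_trace` (a data frame with the
#'   `strain_step` attribute).
#' @export
relaxation_trace <- function(times, relaxation_modulus, strain_step = 0.001) {
  if (length(times) != length(relaxation_modulus))
    stop("relaxation_trace: column lengths differ", call. = FALSE)
  if (any(!is.finite(times)) || any(times <= 0) ||
      is.unsorted(times, strictly = TRUE))
    stop("relaxation_trace: times must be positive and strictly increasing",
         call. = FALSE)
  if (any(relaxation_modulus <= 0))
    stop("relaxation_trace: moduli must be positive", call. = FALSE)
  structure(data.frame(time = times, relaxation_modulus = relaxation_modulus),
            strain_step = strain_step,
            class = c("relaxation_trace", "data.frame"))
}

#' Predict step-strain relaxation from springpot parameters
#'
#' Evaluates the power-law relaxation modulus
#' `G(t) = K_alpha * t^(-alpha) / Gamma(1 - alpha)` pointwise (the dashpot's
#' impulse at `t = 0` is excluded; see [sfkv_relaxation_modulus()]).
#'
#' @param params An [sfkv_params()] object (typically from a frequency-domain
#'   fit).
#' @param times Seconds, all positive.
#' @return A [relaxation_trace()] of predicted moduli.
#' @export
predict_relaxation <- function(params, times) {
  relaxation_trace(times, sfkv_relaxation_modulus(params, times))
}

#' Compare a predicted relaxation curve against a measured one
#'
#' Two aspects are separated: the initial amplitude and the decay shape.
#' `initial_discrepancy` is the signed percentage
#' `(predicted - measured) / measured * 100` at the earliest common time
#' (1 s in the study protocol), so "predicted 29% less than measured" reads
#' as -29. `decay_shape_distance` is the maximum relative deviation (in %)
#' between the two curves after each is divided by its own value at that
#' initial time — zero whenever the curves differ only by a constant factor.
#'
#' @param predicted,measured [relaxation_trace()] objects; compared on the
#'   intersection of their time grids.
#' @return An object of class `relaxation_comparison`: `times`, `predicted`,
#'   `measured` (aligned series, kPa), `initial_discrepancy` (%),
#'   `decay_shape_distance` (%).
#' @export
compare_relaxation <- function(predicted, measured) {
  stopifnot(inherits(predicted, "relaxation_trace"),
            inherits(measured, "relaxation_trace"))
  common <- intersect(predicted$time, measured$time)
  if (!length(common))
    stop("compare_relaxation: no overlapping times", call. = FALSE)
  common <- sort(common)
  p <- predicted$relaxation_modulus[match(common, predicted$time)]
  m <- measured$relaxation_modulus[match(common, measured$time)]
  disc <- (p[1] - m[1]) / m[1] * 100
  pn <- p / p[1]; mn <- m / m[1]
  shape <- max(abs(pn - mn) / mn) * 100
  structure(list(times = common, predicted = p, measured = m,
                 initial_discrepancy = disc,
                 decay_shape_distance = shape),
            class = "relaxation_comparison")
}

#' @export
print.relaxation_comparison <- function(x, ...) {
  cat(sprintf(
    "Relaxation comparison over t = %g..%g s:\n  initial (t = %g s) discrepancy: %+.1f%% (predicted vs measured)\n  decay-shape distance: %.2f%%\n",
    min(x$times), max(x$times), x$times[1], x$initial_discrepancy,
    x$decay_shape_distance))
  invisible(x)
}

#' Extrapolate the storage modulus to arbitrary frequencies
#'
#' Evaluates the springpot+dashpot storage modulus at the given frequencies
#' (e.g. the bands used by elastography studies) and, when a range is given,
#' summarizes it by its endpoint values rounded half-up to `digits`
#' decimals — the storage modulus is monotone in frequency, so the endpoints
#' bound the band.
#'
#' @param params An [sfkv_params()] object.
#' @param frequencies Hz; either a vector of evaluation points or a length-2
#'   range `c(fmin, fmax)` when `range = TRUE`.
#' @param convention `"hz"` (default) or `"rad"`.
#' @param digits Rounding for the `rounded` column / range summary.
#' @return A data frame with columns `frequency`, `storage` (kPa, exact) and
#'   `rounded`; attribute `range_summary` holds the "lo-hi" string when a
#'   range was requested.
#' @examples
#' heart <- sfkv_params(2.00, 0.13, 10.3)
#' extrapolate_storage(heart, 80)              # MRE frequency
#' extrapolate_storage(heart, c(40, 500), range = TRUE)
#' @export
extrapolate_storage <- function(params, frequencies, convention = "hz",
                                digits = 2, range = FALSE) {
  cm <- sfkv_complex_modulus(params, frequencies, convention)
  out <- data.frame(frequency = cm$frequency, storage = cm$storage,
                    rounded = round_half_up(cm$storage, digits))
  if (range) {
    if (length(frequencies) != 2)
      stop("extrapolate_storage: range = TRUE needs c(fmin, fmax)",
           call. = FALSE)
    attr(out, "range_summary") <- paste(format(out$rounded, trim = TRUE),
                                        collapse = "-")
  }
  out
}
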