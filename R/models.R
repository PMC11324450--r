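# Closed-form frequency- and time-domain responses of the springpot-based
# viscoelastic models, plus a Grunwald-Letnikov numerical oracle.
#
# Unit conventions used throughout the package:
#   * moduli and springpot consistence K_alpha are carried in kPa (kPa.s^alpha),
#     matching how rheometer exports and the fitted tables are reported;
#   * dashpot viscosities eta are carried in Pa.s, so the viscous loss term is
#     eta * f / 1000 kPa;
#   * "hz" convention evaluates the power laws with ordinary frequency f in Hz,
#     "rad" with angular frequency 2*pi*f. See the methods vignette for why
#     "hz" is the default.

#' Springpot + dashpot (semi-fractional Kelvin-Voigt) parameters
#'
#' A springpot (Scott-Blair element, stress proportional to the alpha-th
#' fractional derivative of strain) in parallel with a dashpot. The springpot
#' interpolates between a spring (`alpha = 0`, `k_alpha` a modulus) and a
#' dashpot (`alpha = 1`, `k_alpha` a viscosity).
#'
#' @param k_alpha Coefficient of consistence, kPa.s^alpha. Must be positive.
#' @param alpha Fractional order, in `[0, 1]`.
#' @param eta Parallel dashpot viscosity, Pa.s. Non-negative.
#' @return An object of class `sfkv_params`.
#' @examples
#' sfkv_params(k_alpha = 0.88, alpha = 0.12, eta = 7.58) # porcine kidney scale
#' @export
sfkv_params <- function(k_alpha, alpha, eta = 0) {
  check_scalar(k_alpha, "k_alpha", lower = 0, open_lower = TRUE)
  check_scalar(alpha, "alpha", lower = 0, upper = 1)
  check_scalar(eta, "eta", lower = 0)
  structure(list(k_alpha = k_alpha, alpha = alpha, eta = eta),
            class = c("sfkv_params", "rheo_params"))
}

#' Springpot + spring (fractional Kelvin-Voigt) parameters
#'
#' @param k_alpha Coefficient of consistence, kPa.s^alpha. Positive.
#' @param alpha Fractional order, in `[0, 1]`.
#' @param g Parallel spring modulus, kPa. Non-negative.
#' @return An object of class `fkv_params`.
#' @export
fkv_params <- function(k_alpha, alpha, g) {
  check_scalar(k_alpha, "k_alpha", lower = 0, open_lower = TRUE)
  check_scalar(alpha, "alpha", lower = 0, upper = 1)
  check_scalar(g, "g", lower = 0)
  structure(list(k_alpha = k_alpha, alpha = alpha, g = g),
            class = c("fkv_params", "rheo_params"))
}

#' Standard linear solid (Zener) parameters
#'
#' Spring `g1` in parallel with a Maxwell arm (spring `g2` in series with a
#' dashpot `eta`).
#'
#' @param g1 Parallel spring modulus, kPa.
#' @param g2 Series-arm spring modulus, kPa.
#' @param eta Series-arm viscosity, Pa.s.
#' @return An object of class `sls_params`.
#' @export
sls_params <- function(g1, g2, eta) {
  check_scalar(g1, "g1", lower = 0)
  check_scalar(g2, "g2", lower = 0)
  check_scalar(eta, "eta", lower = 0)
  if (g2 == 0 && eta > 0)
    stop("sls_params: eta > 0 requires g2 > 0 (series arm needs a spring)",
         call. = FALSE)
  structure(list(g1 = g1, g2 = g2, eta = eta),
            class = c("sls_params", "rheo_params"))
}

#' @export
print.rheo_params <- function(x, ...) {
  cat(sprintf("<%s> %s\n", class(x)[1],
              paste(sprintf("%s = %g", names(x), unlist(x)), collapse = ", ")))
  invisible(x)
}

# effective frequency entering the power laws: f for "hz", 2*pi*f for "rad"
effective_frequency <- function(frequency, convention) {
  convention <- match.arg(convention, c("hz", "rad"))
  if (convention == "hz") frequency else 2 * pi * frequency
}

complex_modulus_frame <- function(frequency, storage, loss) {
  data.frame(frequency = frequency, storage = storage, loss = loss)
}

#' Complex modulus of the springpot + dashpot model
#'
#' Storage modulus `G' = K_alpha * w^alpha * cos(alpha*pi/2)` and loss modulus
#' `G'' = K_alpha * w^alpha * sin(alpha*pi/2) + eta*w`, where `w` is the
#' frequency in the chosen convention (`"hz"`: ordinary frequency in Hz,
#' the package default; `"rad"`: angular frequency).
#'
#' @param params An [sfkv_params()] object.
#' @param frequency Frequencies, Hz. All positive.
#' @param convention `"hz"` or `"rad"`; see the methods vignette.
#' @return A data frame with columns `frequency` (Hz), `storage` (kPa),
#'   `loss` (kPa).
#' @examples
#' # porcine heart fit evaluated at an elastography frequency
#' sfkv_complex_modulus(sfkv_params(2.00, 0.13), 80)
#' @export
sfkv_complex_modulus <- function(params, frequency, convention = "hz") {
  stopifnot(inherits(params, "sfkv_params"))
  check_frequencies(frequency)
  w <- effective_frequency(frequency, convention)
  pow <- params$k_alpha * w^params$alpha
  complex_modulus_frame(frequency,
                        storage = pow * cos(params$alpha * pi / 2),
                        loss = pow * sin(params$alpha * pi / 2) +
                          params$eta * w / 1000)
}

#' Complex modulus of the springpot + spring model
#'
#' `G' = K_alpha * w^alpha * cos(alpha*pi/2) + G`,
#' `G'' = K_alpha * w^alpha * sin(alpha*pi/2)`.
#'
#' @inheritParams sfkv_complex_modulus
#' @param params An [fkv_params()] object.
#' @return A data frame with columns `frequency`, `storage`, `loss` (kPa).
#' @export
fkv_complex_modulus <- function(params, frequency, convention = "hz") {
  stopifnot(inherits(params, "fkv_params"))
  check_frequencies(frequency)
  w <- effective_frequency(frequency, convention)
  pow <- params$k_alpha * w^params$alpha
  complex_modulus_frame(frequency,
                        storage = pow * cos(params$alpha * pi / 2) + params$g,
                        loss = pow * sin(params$alpha * pi / 2))
}

#' Complex modulus of the standard linear solid (Zener) model
#'
#' With relaxation time `tau = eta / g2` (seconds; `eta` converted to kPa.s so
#' the ratio is in s):
#' `G' = g1 + g2 * (w*tau)^2 / (1 + (w*tau)^2)`,
#' `G'' = g2 * w*tau / (1 + (w*tau)^2)`.
#'
#' @inheritParams sfkv_complex_modulus
#' @param params An [sls_params()] object.
#' @return A data frame with columns `frequency`, `storage`, `loss` (kPa).
#' @export
sls_complex_modulus <- function(params, frequency, convention = "hz") {
  stopifnot(inherits(params, "sls_params"))
  check_frequencies(frequency)
  w <- effective_frequency(frequency, convention)
  if (params$g2 == 0) {
    return(complex_modulus_frame(frequency,
                                 storage = rep(params$g1, length(frequency)),
                                 loss = rep(0, length(frequency))))
  }
  tau <- (params$eta / 1000) / params$g2   # Pa.s -> kPa.s over kPa gives s
  wt <- w * tau
  complex_modulus_frame(frequency,
                        storage = params$g1 + params$g2 * wt^2 / (1 + wt^2),
                        loss = params$g2 * wt / (1 + wt^2))
}

#' Complex modulus (generic dispatch over the three models)
#'
#' @param params One of [sfkv_params()], [fkv_params()], [sls_params()].
#' @param frequency Frequencies, Hz.
#' @param convention `"hz"` or `"rad"`.
#' @return A data frame with columns `frequency`, `storage`, `loss`.
#' @export
complex_modulus <- function(params, frequency, convention = "hz") {
  UseMethod("complex_modulus")
}

#' @export
complex_modulus.sfkv_params <- function(params, frequency, convention = "hz")
  sfkv_complex_modulus(params, frequency, convention)

#' @export
complex_modulus.fkv_params <- function(params, frequency, convention = "hz")
  fkv_complex_modulus(params, frequency, convention)

#' @export
complex_modulus.sls_params <- function(params, frequency, convention = "hz")
  sls_complex_modulus(params, frequency, convention)

#' Relaxation modulus of the springpot + dashpot model
#'
#' Response to a step strain `e0 * H(t)`:
#' `G(t) = eta * delta(t) + K_alpha * t^(-alpha) / Gamma(1 - alpha)`.
#' The dashpot contributes only the impulse at `t = 0`, which is excluded
#' here; evaluation therefore requires `t > 0`. For `0 < alpha < 1` the
#' modulus decays as a pure power law, so `G(t1)/G(t2) = (t2/t1)^alpha`.
#'
#' @param params An [sfkv_params()] object.
#' @param t Times after the step, seconds. All strictly positive.
#' @return Relaxation modulus, kPa, same length as `t`.
#' @examples
#' sfkv_relaxation_modulus(sfkv_params(0.88, 0.12, 7.58), 1:10)
#' @export
sfkv_relaxation_modulus <- function(params, t) {
  stopifnot(inherits(params, "sfkv_params"))
  if (!is.numeric(t) || any(!is.finite(t)) || any(t <= 0))
    stop("sfkv_relaxation_modulus: all times must be finite and > 0 ",
         "(the impulse term is defined only at t = 0)", call. = FALSE)
  params$k_alpha * t^(-params$alpha) / gamma(1 - params$alpha)
}

#' Strain history for time-domain simulation
#'
#' @param times Sample times, seconds, strictly increasing from 0.
#' @param strains Dimensionless shear strain at each time.
#' @param strain_amplitude Nominal amplitude `e0` (dimensionless), used when
#'   normalizing step responses. Defaults to `max(abs(strains))`.
#' @return An object of class `strain_history`.
#' @export
strain_history <- function(times, strains,
                           strain_amplitude = max(abs(strains))) {
  if (length(times) != length(strains))
    stop("strain_history: times and strains must have equal length",
         call. = FALSE)
  if (any(!is.finite(times)) || any(times < 0) || is.unsorted(times, strictly = TRUE))
    stop("strain_history: times must be non-negative and strictly increasing",
         call. = FALSE)
  structure(list(times = times, strains = strains,
                 strain_amplitude = strain_amplitude),
            class = "strain_history")
}

#' Step strain history
#'
#' `e(t) = e0 * H(t)` sampled on a uniform grid; a convenience for
#' relaxation-test simulation.
#'
#' @param strain_amplitude Step amplitude `e0`, dimensionless (0.001 = 0.1%).
#' @param t_end Last sample time, s.
#' @param dt Grid spacing, s.
#' @return A [strain_history()] covering `seq(0, t_end, by = dt)`.
#' @export
step_strain_history <- function(strain_amplitude, t_end, dt) {
  times <- seq(0, t_end, by = dt)
  strain_history(times, rep(strain_amplitude, length(times)),
                 strain_amplitude = strain_amplitude)
}

#' Time-domain stress via the Grunwald-Letnikov discretization
#'
#' Numerical oracle for the springpot + dashpot constitutive law
#' `sigma(t) = K_alpha * D^alpha e(t) + eta * de/dt`. The fractional
#' derivative is discretized with first-order Grunwald-Letnikov weights
#' `w_0 = 1`, `w_j = w_{j-1} * (j - 1 - alpha) / j` over the full history
#' (no short-memory truncation); the dashpot term uses a backward
#' difference. The convolution is evaluated with an FFT, so traces of 1e4+
#' steps are cheap.
#'
#' For a step strain the normalized stress `sigma(t)/e0` converges to
#' [sfkv_relaxation_modulus()] as `dt -> 0`.
#'
#' @param params An [sfkv_params()] object.
#' @param history A [strain_history()]; resampled to the `dt` grid by linear
#'   interpolation (constant extrapolation at the ends).
#' @param dt Uniform time step, s. Must not exceed the finest spacing of
#'   `history$times`.
#' @return A data frame with columns `time` (s) and `stress` (kPa), on the
#'   uniform grid `seq(dt, max(times), by = dt)` (the `t = 0` point carries
#'   the unresolved impulse and is omitted).
#' @export
gl_stress_response <- function(params, history, dt) {
  stopifnot(inherits(params, "sfkv_params"), inherits(history, "strain_history"))
  check_scalar(dt, "dt", lower = 0, open_lower = TRUE)
  min_gap <- min(diff(history$times))
  if (length(history$times) > 1 && dt > min_gap + 1e-12)
    stop("gl_stress_response: dt exceeds the finest spacing of the history (",
         signif(min_gap, 3), " s); refine dt", call. = FALSE)
  t_end <- max(history$times)
  n <- floor(t_end / dt + 1e-9)
  grid <- (0:n) * dt
  eps <- stats::approx(history$times, history$strains, xout = grid,
                       rule = 2)$y
  alpha <- params$alpha
  # GL weights w_j = (-1)^j * choose(alpha, j), via the stable recurrence
  j <- seq_len(n)
  w <- cumprod(c(1, (j - 1 - alpha) / j))
  conv <- gl_convolve(w, eps)
  frac <- conv * dt^(-alpha)
  rate <- c(eps[1] / dt, diff(eps) / dt)   # strain assumed 0 before t = 0
  stress <- params$k_alpha * frac + params$eta / 1000 * rate
  data.frame(time = grid[-1], stress = stress[-1])
}

# causal convolution sum_{j<=n} w_j * x_{n-j}; FFT for long series
gl_convolve <- function(w, x) {
  n <- length(x)
  if (n < 256) {
    out <- numeric(n)
    for (i in seq_len(n)) out[i] <- sum(w[1:i] * x[i:1])
    return(out)
  }
  m <- stats::nextn(2 * n - 1, 2)
  wp <- c(w, numeric(m - n)); xp <- c(x, numeric(m - n))
  full <- Re(stats::fft(stats::fft(wp) * stats::fft(xp), inverse = TRUE)) / m
  full[1:n]
}
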