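# Seeded generator of rheometer-like datasets: frequency sweeps with
# power-law structure and an optional high-frequency inertial artifact,
# strain sweeps with an LVE plateau and amplitude softening, and step-strain
# relaxation traces. Defaults are the four porcine-organ profiles of the
# study the package models.

# evaluate a block with a temporary RNG state; global stream untouched
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Fitted organ profiles: springpot+dashpot parameters at the 0.1 N contact
# state, the linear K_alpha(strain) law, the per-strain alpha/eta drift,
# LVE limit, inertial onset and elastic modulus.
organ_profile_data <- list(
  heart = list(params = c(2.00, 0.13, 10.3), k0 = 1.94, b = 0.10,
               elastic_modulus = 110, inertial_onset = 9.5,
               drift_alpha = c(0.13, 0.11, 0.11, 0.11, 0.11, 0.10),
               drift_eta = c(10.3, 18.4, 17.6, 21.2, 20.6, 25.6)),
  kidney = list(params = c(0.88, 0.12, 7.58), k0 = 0.69, b = 0.23,
                elastic_modulus = 44, inertial_onset = 9.5,
                drift_alpha = c(0.12, 0.11, 0.10, 0.10, 0.09, 0.09),
                drift_eta = c(7.58, 10.9, 13.5, 14.3, 20.1, 22.1)),
  liver = list(params = c(0.27, 0.16, 9.70), k0 = 0.26, b = 0.12,
               elastic_modulus = 17.5, inertial_onset = 4.2,
               drift_alpha = c(0.16, 0.14, 0.14, 0.13, 0.13, 0.13),
               drift_eta = c(9.70, 13.1, 13.4, 16.1, 14.6, 17.5)),
  brain = list(params = c(0.25, 0.16, 10.5), k0 = 0.13, b = 0.07,
               elastic_modulus = 1.5, inertial_onset = 2.8,
               drift_alpha = c(0.16, 0.15, 0.15, 0.15, 0.15, 0.15),
               drift_eta = c(10.5, 13.2, 13.0, 13.2, 12.4, 12.3))
)
drift_strains <- c(0.5, 2.5, 4.5, 6.5, 8.5, 10.5)

#' Built-in organ profile
#'
#' Ground-truth generator settings for one of the four porcine organs:
#' springpot+dashpot parameters at the reference contact state, the linear
#' consistence-vs-axial-strain law `K_alpha = k0 (1 + b eps_A)`, tables of
#' how `alpha` and `eta` drift with pre-strain, the LVE strain limit (0.1%),
#' the inertial onset frequency, the measurement noise level and the
#' elastic modulus used for contact-strain conversion.
#'
#' @param organ `"heart"`, `"kidney"`, `"liver"` or `"brain"`.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise. Default 0.03.
#' @return An object of class `organ_profile`.
#' @examples
#' organ_profile("kidney")
#' @export
organ_profile <- function(organ = c("heart", "kidney", "liver", "brain"),
                          noise_cv = 0.03) {
  organ <- match.arg(organ)
  d <- organ_profile_data[[organ]]
  structure(list(
    organ = organ,
    params = sfkv_params(d$params[1], d$params[2], d$params[3]),
    k0 = d$k0, b = d$b,
    drift = data.frame(axial_strain = drift_strains,
                       alpha = d$drift_alpha, eta = d$drift_eta),
    lve_limit = 0.1, inertial_onset = d$inertial_onset,
    noise_cv = noise_cv, elastic_modulus = d$elastic_modulus),
    class = "organ_profile")
}

#' @export
print.organ_profile <- function(x, ...) {
  cat(sprintf(
    "<organ_profile> %s: K_alpha = %.2f kPa.s^a, alpha = %.2f, eta = %.2f Pa.s\n  K(eps) = %.2f (1 + %.2f eps), LVE <= %.2g%%, inertial onset %.1f Hz, E = %.1f kPa\n",
    x$organ, x$params$k_alpha, x$params$alpha, x$params$eta, x$k0, x$b,
    x$lve_limit, x$inertial_onset, x$elastic_modulus))
  invisible(x)
}

# springpot params at a given axial pre-strain: K from the linear law;
# alpha/eta either held at the reference values or interpolated from the
# drift table
profile_params_at <- function(profile, axial_strain, use_drift = FALSE) {
  k <- profile$k0 * (1 + profile$b * axial_strain)
  if (use_drift) {
    a <- stats::approx(profile$drift$axial_strain, profile$drift$alpha,
                       xout = axial_strain, rule = 2)$y
    e <- stats::approx(profile$drift$axial_strain, profile$drift$eta,
                       xout = axial_strain, rule = 2)$y
  } else {
    a <- profile$params$alpha
    e <- profile$params$eta
  }
  sfkv_params(k, a, e)
}

#' Simulate a frequency sweep
#'
#' Clean moduli follow the springpot+dashpot frequency response; both
#' channels are then multiplied by independent lognormal noise with unit
#' mean and coefficient of variation `noise_cv`. If the frequency range
#' extends past the profile's inertial onset, the instrument-inertia
#' artifact is emulated: the onset frequency is inserted into the grid, and
#' strictly above it the storage modulus is suppressed by
#' `1 / (1 + (f/f_onset)^4)` (a growing dip) while the loss modulus picks
#' up an extra term growing as `f^2`. Points at and below the onset stay
#' clean, matching how the usable band of an inertia-limited sweep runs up
#' to the onset. The artifact shape mimics the appearance of such sweeps
#' and makes no physical claim.
#'
#' @param profile An [organ_profile()].
#' @param axial_strain Axial pre-strain, percent, or `NULL` (default) to use
#'   the profile's reference fitted parameters directly. When given, the
#'   consistence follows `k0 (1 + b eps_A)`; with `use_drift = TRUE`,
#'   `alpha` and `eta` are interpolated from the profile drift table.
#' @param n_points Number of log-spaced frequencies. Default 20.
#' @param f_range `c(fmin, fmax)` in Hz. Default `c(0.1, 9.5)`, the study's
#'   sweep band.
#' @param noise_cv Noise level; defaults to the profile's. 0 gives the exact
#'   model values.
#' @param seed Integer seed for reproducibility (the global RNG stream is
#'   left untouched).
#' @param use_drift Interpolate `alpha`/`eta` from the drift table when
#'   `axial_strain` is given. Default `FALSE` (pure consistence scaling).
#' @param params Optional [sfkv_params()] overriding the profile truth
#'   entirely.
#' @return A [frequency_sweep()]; attribute `true_params` records the
#'   generating parameters.
#' @export
gen_frequency_sweep <- function(profile, axial_strain = NULL, n_points = 20,
                                f_range = c(0.1, 9.5),
                                noise_cv = profile$noise_cv, seed = NULL,
                                use_drift = FALSE, params = NULL) {
  stopifnot(inherits(profile, "organ_profile"))
  if (n_points < 5) stop("gen_frequency_sweep: n_points >= 5", call. = FALSE)
  check_frequencies(f_range)
  if (is.null(params))
    params <- if (is.null(axial_strain)) profile$params
              else profile_params_at(profile, axial_strain, use_drift)
  f <- exp(seq(log(f_range[1]), log(f_range[2]), length.out = n_points))
  f[c(1, n_points)] <- f_range   # undo exp(log()) round-off at the ends
  onset <- profile$inertial_onset
  if (f_range[2] > onset && f_range[1] < onset)
    f <- sort(unique(c(f, onset)))
  cm <- sfkv_complex_modulus(params, f)
  storage <- cm$storage; loss <- cm$loss
  hi <- f > onset * (1 + 1e-9)
  if (any(hi)) {
    storage[hi] <- storage[hi] / (1 + (f[hi] / onset)^4)
    loss_onset <- sfkv_complex_modulus(params, onset)$loss
    loss[hi] <- loss[hi] + 0.05 * loss_onset * (f[hi] / onset)^2
  }
  with_seed(seed, {
    storage <- storage * lognormal_noise(length(f), noise_cv)
    loss <- loss * lognormal_noise(length(f), noise_cv)
  })
  out <- frequency_sweep(f, storage, loss, strain_amplitude = 0.1,
                         axial_strain = if (is.null(axial_strain)) NA_real_
                                        else axial_strain)
  attr(out, "true_params") <- params
  out
}

#' Simulate an amplitude (strain) sweep
#'
#' Below the profile's LVE limit the moduli sit on a plateau (the 1 Hz
#' springpot+dashpot values); above it both soften along a Kraus-type decay
#' `G(gamma) = G_plateau / (1 + (gamma/gamma_c)^m)`. The crossover
#' `gamma_c` is placed so the relative departure from the plateau reaches
#' `onset_frac` exactly at the LVE limit, which makes the generated limit
#' recoverable by [detect_lve_limit()] run at the same tolerance.
#'
#' @param profile An [organ_profile()].
#' @param n_points Number of log-spaced amplitudes. Default 25.
#' @param strain_range `c(min, max)` percent; must span the LVE limit.
#'   Default `c(0.01, 10)`, the study's sweep.
#' @param noise_cv Noise level; defaults to the profile's.
#' @param seed Integer seed.
#' @param m Softening exponent. Default 0.8.
#' @param onset_frac Relative departure from the plateau at the LVE limit.
#'   Default 0.05.
#' @return A [strain_sweep()] at 1 Hz.
#' @export
gen_strain_sweep <- function(profile, n_points = 25, strain_range = c(0.01, 10),
                             noise_cv = profile$noise_cv, seed = NULL,
                             m = 0.8, onset_frac = 0.05) {
  stopifnot(inherits(profile, "organ_profile"))
  if (strain_range[1] >= profile$lve_limit ||
      strain_range[2] <= profile$lve_limit)
    stop("gen_strain_sweep: strain_range must span the LVE limit",
         call. = FALSE)
  gam <- exp(seq(log(strain_range[1]), log(strain_range[2]),
                 length.out = n_points))
  cm <- sfkv_complex_modulus(profile$params, 1)
  gamma_c <- profile$lve_limit * ((1 - onset_frac) / onset_frac)^(1 / m)
  soften <- 1 / (1 + (gam / gamma_c)^m)
  with_seed(seed, {
    storage <- cm$storage * soften * lognormal_noise(n_points, noise_cv)
    loss <- cm$loss * soften * lognormal_noise(n_points, noise_cv)
  })
  strain_sweep(gam, storage, loss, frequency = 1)
}

#' Simulate a step-strain relaxation trace
#'
#' The clean trace is the power-law relaxation modulus of the profile's
#' springpot parameters, optionally scaled by a constant `bias` factor to
#' emulate the initial-amplitude mismatch seen between frequency-domain
#' predictions and measured relaxation (up to ~30% in the organ study),
#' then multiplied by lognormal noise.
#'
#' @param profile An [organ_profile()].
#' @param times Sample times, s. Default `1:10` (1 s sampling for 10 s).
#' @param strain_step Step amplitude, dimensionless. Default 0.001 (0.1%).
#' @param noise_cv Noise level; defaults to the profile's.
#' @param bias Constant amplitude factor. Default 1 (no mismatch).
#' @param seed Integer seed.
#' @return A [relaxation_trace()].
#' @export
gen_relaxation_trace <- function(profile, times = 1:10, strain_step = 0.001,
                                 noise_cv = profile$noise_cv, bias = 1,
                                 seed = NULL) {
  stopifnot(inherits(profile, "organ_profile"))
  check_scalar(bias, "bias", lower = 0, open_lower = TRUE)
  clean <- bias * sfkv_relaxation_modulus(profile$params, times)
  mod <- with_seed(seed, clean * lognormal_noise(length(times), noise_cv))
  relaxation_trace(times, mod, strain_step)
}

#' Simulate a full rheometer session for one organ
#'
#' One strain sweep, frequency sweeps at the six pre-strain levels of the
#' study design, and a relaxation trace, all driven from a single seed
#' (sub-seeds are derived deterministically, so regeneration with the same
#' seed is identical).
#'
#' @param profile An [organ_profile()].
#' @param seed Integer seed.
#' @param axial_strains Pre-strain levels, percent. Default
#'   `c(0.5, 2.5, 4.5, 6.5, 8.5, 10.5)`.
#' @return A list of class `synthetic_dataset`: `strain_sweep`,
#'   `frequency_sweeps` (named by strain), `relaxation`, `geometry`, `seed`.
#' @export
gen_dataset <- function(profile, seed = 1,
                        axial_strains = c(0.5, 2.5, 4.5, 6.5, 8.5, 10.5)) {
  stopifnot(inherits(profile, "organ_profile"))
  sub <- function(k) (seed * 1000L + k) %% .Machine$integer.max
  fs <- lapply(seq_along(axial_strains), function(i)
    gen_frequency_sweep(profile, axial_strain = axial_strains[i],
                        seed = sub(i)))
  names(fs) <- paste0("strain_", axial_strains)
  structure(list(
    strain_sweep = gen_strain_sweep(profile, seed = sub(100)),
    frequency_sweeps = fs,
    relaxation = gen_relaxation_trace(profile, seed = sub(200)),
    geometry = sample_geometry(diameter = 25, thickness = 5.5,
                               elastic_modulus = profile$elastic_modulus,
                               contact_force = 0.1, organ = profile$organ),
    seed = seed), class = "synthetic_dataset")
}
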