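# Pre-fit data-quality stages: linear-viscoelastic (LVE) region detection
# from strain sweeps, inertial-artifact truncation of frequency sweeps, and
# contact-force -> axial-strain conversion.

#' Amplitude (strain) sweep container
#'
#' Storage and loss moduli recorded while the shear-strain amplitude is
#' stepped up at a fixed oscillation frequency (1 Hz in the organ study).
#'
#' @param strain_amplitudes Shear-strain amplitudes, percent, strictly
#'   increasing.
#' @param storage Storage modulus G', kPa, one per amplitude.
#' @param loss Loss modulus G'', kPa, one per amplitude.
#' @param frequency Oscillation frequency, Hz.
#' @return An object of class `strain_sweep` (a data frame with attributes).
#' @export
strain_sweep <- function(strain_amplitudes, storage, loss, frequency = 1) {
  n <- length(strain_amplitudes)
  if (length(storage) != n || length(loss) != n)
    stop("strain_sweep: column lengths differ", call. = FALSE)
  if (any(!is.finite(strain_amplitudes)) ||
      is.unsorted(strain_amplitudes, strictly = TRUE))
    stop("strain_sweep: strain amplitudes must be strictly increasing",
         call. = FALSE)
  if (any(storage <= 0) || any(loss < 0))
    stop("strain_sweep: moduli must be positive", call. = FALSE)
  check_scalar(frequency, "frequency", lower = 0, open_lower = TRUE)
  structure(data.frame(strain_pct = strain_amplitudes,
                       storage = storage, loss = loss),
            frequency = frequency,
            class = c("strain_sweep", "data.frame"))
}

#' Frequency sweep container
#'
#' Storage and loss moduli recorded over increasing oscillation frequency at
#' fixed strain amplitude and axial pre-compression.
#'
#' @param frequencies Hz, strictly increasing.
#' @param storage Storage modulus G', kPa.
#' @param loss Loss modulus G'', kPa.
#' @param strain_amplitude Shear-strain amplitude, percent (0.1 in the study).
#' @param contact_force Axial contact force, N (optional).
#' @param axial_strain Axial pre-strain, percent (optional).
#' @return An object of class `frequency_sweep` (a data frame with
#'   attributes). The logical column `included` marks points used for
#'   fitting; [truncate_inertial()] clears it above the inertial cutoff.
#' @export
frequency_sweep <- function(frequencies, storage, loss,
                            strain_amplitude = 0.1,
                            contact_force = NA_real_,
                            axial_strain = NA_real_) {
  n <- length(frequencies)
  if (length(storage) != n || length(loss) != n)
    stop("frequency_sweep: column lengths differ", call. = FALSE)
  check_frequencies(frequencies)
  if (is.unsorted(frequencies, strictly = TRUE))
    stop("frequency_sweep: frequencies must be strictly increasing",
         call. = FALSE)
  if (any(storage <= 0) || any(loss < 0))
    stop("frequency_sweep: moduli must be positive", call. = FALSE)
  structure(data.frame(frequency = frequencies, storage = storage,
                       loss = loss, included = TRUE),
            strain_amplitude = strain_amplitude,
            contact_force = contact_force,
            axial_strain = axial_strain,
            class = c("frequency_sweep", "data.frame"))
}

#' Sample geometry and loading state
#'
#' @param diameter Sample diameter, mm.
#' @param thickness Sample thickness, mm.
#' @param elastic_modulus Uniaxial elastic modulus E, kPa (measured
#'   independently by compression testing or taken from literature).
#' @param contact_force Axial contact force, N.
#' @param organ Label.
#' @param temperature Test temperature, degrees C.
#' @return An object of class `sample_geometry`.
#' @export
sample_geometry <- function(diameter, thickness, elastic_modulus,
                            contact_force, organ = NA_character_,
                            temperature = 20) {
  check_scalar(diameter, "diameter", lower = 0, open_lower = TRUE)
  check_scalar(thickness, "thickness", lower = 0, open_lower = TRUE)
  check_scalar(elastic_modulus, "elastic_modulus", lower = 0, open_lower = TRUE)
  check_scalar(contact_force, "contact_force", lower = 0)
  structure(list(diameter = diameter, thickness = thickness,
                 elastic_modulus = elastic_modulus,
                 contact_force = contact_force, organ = organ,
                 temperature = temperature),
            class = "sample_geometry")
}

#' Detect the linear viscoelastic strain limit
#'
#' The LVE limit is the largest strain amplitude up to which the storage
#' modulus stays on the low-strain plateau. The plateau reference is the mean
#' G' of the first three points; the limit is the largest amplitude such that
#' every G' at or below it deviates from the reference by less than
#' `tolerance` (relative). If no point deviates the maximum amplitude is
#' returned. Only G' is used: it dominates the plateau and is less noisy than
#' G''.
#'
#' @param sweep A [strain_sweep()].
#' @param tolerance Allowed relative deviation, in `(0, 0.5)`. Default 0.05.
#' @return LVE strain limit, percent.
#' @export
detect_lve_limit <- function(sweep, tolerance = 0.05) {
  stopifnot(inherits(sweep, "strain_sweep"))
  if (nrow(sweep) < 4)
    stop("detect_lve_limit: need at least 4 points", call. = FALSE)
  check_scalar(tolerance, "tolerance", lower = 0, upper = 0.5,
               open_lower = TRUE)
  ref <- mean(sweep$storage[1:3])
  dev <- abs(sweep$storage / ref - 1)
  bad <- which(dev >= tolerance)
  if (length(bad) == 0) return(sweep$strain_pct[nrow(sweep)])
  if (bad[1] == 1)
    stop("detect_lve_limit: first point already off its own plateau ",
         "reference; sweep looks nonlinear from the start", call. = FALSE)
  sweep$strain_pct[bad[1] - 1]
}

#' Detect the inertial bandwidth limit of a frequency sweep
#'
#' Instrument inertia shows up at high frequency as a drop in G' (and a rise
#' in G''). The cutoff is the lowest frequency at which G' falls below its
#' running maximum by more than `drop_tolerance` (relative). Points at and
#' above the cutoff should be excluded from fitting (see
#' [truncate_inertial()]).
#'
#' @param sweep A [frequency_sweep()].
#' @param drop_tolerance Relative drop from the running maximum that flags
#'   inertia. Default 0.05.
#' @return Cutoff frequency in Hz, or `NA` if no inertial drop is found.
#' @export
detect_inertial_cutoff <- function(sweep, drop_tolerance = 0.05) {
  stopifnot(inherits(sweep, "frequency_sweep"))
  if (nrow(sweep) < 5)
    stop("detect_inertial_cutoff: need at least 5 points", call. = FALSE)
  check_scalar(drop_tolerance, "drop_tolerance", lower = 0, upper = 1,
               open_lower = TRUE)
  runmax <- cummax(sweep$storage)
  drop <- 1 - sweep$storage / runmax
  hit <- which(drop > drop_tolerance)
  if (length(hit) == 0) return(NA_real_)
  sweep$frequency[hit[1]]
}

#' Mask inertia-contaminated points of a frequency sweep
#'
#' Runs [detect_inertial_cutoff()] and clears `included` for all points at
#' and above the cutoff.
#'
#' @inheritParams detect_inertial_cutoff
#' @return The sweep with its `included` column updated and attribute
#'   `inertial_cutoff` set (Hz or `NA`).
#' @export
truncate_inertial <- function(sweep, drop_tolerance = 0.05) {
  cutoff <- detect_inertial_cutoff(sweep, drop_tolerance)
  if (!is.na(cutoff)) sweep$included <- sweep$frequency < cutoff
  attr(sweep, "inertial_cutoff") <- cutoff
  sweep
}

#' Axial stress and strain from the contact force
#'
#' The rheometer presses the upper plate onto the sample with a contact force
#' before oscillating; the resulting pre-compression is
#' `stress = F / (pi * (d/2)^2)` and `strain = stress / E * 100` percent.
#' With `round_stress = TRUE` (default, for parity with reported values) the
#' stress is rounded to the nearest 100 Pa before dividing by E, mirroring
#' the "sigma ~ 200 Pa" working figure of the organ study; set it to `FALSE`
#' for the exact-area value (203.7 Pa for 0.1 N on a 25 mm disc).
#'
#' @param geom A [sample_geometry()].
#' @param round_stress Round the axial stress to the nearest 100 Pa before
#'   computing the strain.
#' @return A list with `axial_stress` (Pa, exact), `axial_strain` (percent),
#'   and `stress_used` (Pa, the value the strain was computed from).
#' @examples
#' g <- sample_geometry(diameter = 25, thickness = 5.3, elastic_modulus = 44,
#'                      contact_force = 0.1, organ = "kidney")
#' contact_axial_state(g)  # ~200 Pa, ~0.5% strain
#' @export
contact_axial_state <- function(geom, round_stress = TRUE) {
  stopifnot(inherits(geom, "sample_geometry"))
  area <- pi * (geom$diameter / 2000)^2          # mm -> m, area in m^2
  if (area <= 0) stop("contact_axial_state: zero contact area", call. = FALSE)
  stress <- geom$contact_force / area            # Pa
  used <- if (round_stress) round(stress / 100) * 100 else stress
  strain <- used / (geom$elastic_modulus * 1000) * 100   # E kPa -> Pa
  list(axial_stress = stress, axial_strain = strain, stress_used = used)
}
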