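# Least-squares fitting of frequency sweeps to the three viscoelastic
# models, model comparison, and the axial-strain dependence of the springpot
# consistence.

model_ids <- c("sfkv", "fkv", "sls")

params_from_vector <- function(model_id, p) {
  switch(model_id,
         sfkv = sfkv_params(max(p[1], 1e-12), min(max(p[2], 0), 1), max(p[3], 0)),
         fkv  = fkv_params(max(p[1], 1e-12), min(max(p[2], 0), 1), max(p[3], 0)),
         sls  = sls_params(max(p[1], 0), max(p[2], 1e-12), max(p[3], 0)))
}

model_curve <- function(model_id, p, frequency, convention) {
  complex_modulus(params_from_vector(model_id, p), frequency, convention)
}

fit_bounds <- function(model_id) {
  if (model_id %in% c("sfkv", "fkv"))
    list(lower = c(1e-12, 0, 0), upper = c(Inf, 1, Inf))
  else
    list(lower = c(0, 1e-12, 0), upper = c(Inf, Inf, Inf))
}

# deterministic starting values from the data (no random restarts)
fit_init <- function(model_id, f, gp, gpp, convention) {
  w <- effective_frequency(f, convention)
  loglog_fit <- function(y) {
    ok <- y > 0
    if (sum(ok) < 2) return(c(slope = 0.1, level = max(mean(y), 1e-6)))
    co <- stats::coef(stats::lm(log(y[ok]) ~ log(w[ok])))
    c(slope = unname(co[2]), level = exp(unname(co[1])))
  }
  clamp <- function(x, lo, hi) min(max(x, lo), hi)
  if (model_id == "sfkv") {
    ll <- loglog_fit(gp)
    a0 <- clamp(ll["slope"], 0.01, 0.95)
    k0 <- ll["level"] / cos(a0 * pi / 2)
    wmax <- max(w)
    resid_loss <- gpp[which.max(w)] - k0 * wmax^a0 * sin(a0 * pi / 2)
    e0 <- max(resid_loss / wmax * 1000, 0.1)
    c(k0, a0, e0)
  } else if (model_id == "fkv") {
    ll <- loglog_fit(gpp)          # loss carries the springpot alone
    a0 <- clamp(ll["slope"], 0.01, 0.95)
    k0 <- max(ll["level"] / sin(a0 * pi / 2), 1e-6)
    g0 <- max(mean(gp - k0 * w^a0 * cos(a0 * pi / 2)), 1e-6)
    c(k0, a0, g0)
  } else {
    g1 <- max(min(gp), 1e-6)
    g2 <- max(max(gp) - min(gp), 0.1 * g1)
    ipk <- which.max(gpp)          # loss peaks at w*tau = 1
    tau <- if (ipk < length(w)) 1 / w[ipk] else 1 / max(w)
    c(g1, g2, tau * g2 * 1000)
  }
}

#' Fit a frequency sweep to a viscoelastic model
#'
#' Joint box-constrained least squares on the storage and loss moduli: the
#' objective is the sum of squared relative residuals of G' and G'' over the
#' `included` points of the sweep (run [truncate_inertial()] first if the
#' sweep reaches into the inertial regime). Relative weighting keeps the
#' smaller loss modulus from being swamped by the storage modulus. Starting
#' values are deterministic, from log-log slopes and endpoint moduli, so the
#' fit is reproducible; `multistart` adds a fixed grid of extra starts for
#' hard cases.
#'
#' The reported `r2` is the coefficient of determination
#' `1 - SS_res / SS_tot` over the concatenated raw (G', G'') vector in kPa,
#' the statistic a joint least-squares fit of both moduli reports; per-channel
#' values are also returned.
#'
#' @param sweep A [frequency_sweep()] (cleaned; at least 5 included points).
#' @param model One of `"sfkv"`, `"fkv"`, `"sls"`.
#' @param convention Frequency convention, `"hz"` (default) or `"rad"`.
#' @param multistart Add a small deterministic grid of alternative starts
#'   and keep the best solution. Default `FALSE`.
#' @return An object of class `fit_result`: fields `model_id`, `params`,
#'   `r2`, `r2_storage`, `r2_loss`, `residual_norm` (root of the summed
#'   squared relative residuals), `n_points`, `convention`, `converged`,
#'   `boundary` (names of parameters that landed on a bound).
#' @examples
#' p <- sfkv_params(0.88, 0.12, 7.58)
#' f <- exp(seq(log(0.1), log(9.5), length.out = 20))
#' cm <- sfkv_complex_modulus(p, f)
#' sw <- frequency_sweep(f, cm$storage, cm$loss)
#' fit_sweep(sw, "sfkv")
#' @export
fit_sweep <- function(sweep, model = c("sfkv", "fkv", "sls"),
                      convention = "hz", multistart = FALSE) {
  stopifnot(inherits(sweep, "frequency_sweep"))
  model <- match.arg(model)
  use <- sweep$included
  f <- sweep$frequency[use]; gp <- sweep$storage[use]; gpp <- sweep$loss[use]
  if (length(f) < 5)
    stop("fit_sweep: need at least 5 included frequencies", call. = FALSE)
  obs <- c(gp, gpp)
  if (stats::sd(obs) == 0)
    warning("fit_sweep: constant moduli; boundary solution likely")
  denom <- pmax(obs, 1e-6 * max(obs))
  resid_fn <- function(p) {
    cm <- model_curve(model, p, f, convention)
    (c(cm$storage, cm$loss) - obs) / denom
  }
  b <- fit_bounds(model)
  starts <- list(fit_init(model, f, gp, gpp, convention))
  if (multistart) {
    base <- starts[[1]]
    for (s1 in c(0.5, 2)) for (s2 in c(0.5, 2))
      starts <- c(starts, list(base * c(s1, s2, 1)))
    starts <- lapply(starts, function(p) pmin(pmax(p, b$lower), b$upper))
  }
  best <- NULL
  for (p0 in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = pmin(pmax(p0, b$lower), b$upper),
                         lower = b$lower, upper = b$upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-15, ptol = 1e-15, maxiter = 500)),
      error = function(e) e)
    if (inherits(res, "error")) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best))
    stop("fit_sweep: optimizer failed for model '", model, "'", call. = FALSE)
  if (best$info == 0 || best$info == 9)
    stop("fit_sweep: optimizer did not converge for model '", model,
         "' (info = ", best$info, "): ", best$message, call. = FALSE)
  p <- best$par
  params <- params_from_vector(model, p)
  cm <- complex_modulus(params, f, convention)
  pred <- c(cm$storage, cm$loss)
  r2 <- function(o, pr) 1 - sum((pr - o)^2) / sum((o - mean(o))^2)
  bnames <- names(unlist(params))
  on_bound <- bnames[(abs(p - b$lower) < 1e-10 & is.finite(b$lower) &
                        b$lower != 0) |
                       (p <= 1e-10) | (abs(p - b$upper) < 1e-10 &
                                         is.finite(b$upper))]
  structure(list(model_id = model, params = params,
                 r2 = r2(obs, pred),
                 r2_storage = r2(gp, cm$storage),
                 r2_loss = r2(gpp, cm$loss),
                 residual_norm = sqrt(best$deviance),
                 n_points = length(f), convention = convention,
                 converged = TRUE, boundary = on_bound),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Model %s fit (%d points, %s convention): r2 = %.4f\n",
              toupper(x$model_id), x$n_points, x$convention, x$r2))
  print(x$params)
  if (length(x$boundary))
    cat("  note: parameter(s) on bound:", paste(x$boundary, collapse = ", "),
        "\n")
  invisible(x)
}

#' Fit and rank all three models on one sweep
#'
#' Fits the springpot+dashpot, springpot+spring and standard-linear-solid
#' models and ranks them by the fit criterion itself — the relative residual
#' norm the least squares minimizes — with `r2` breaking ties. The residual
#' norm weighs the storage and loss channels equally in relative terms;
#' the raw-kPa `r2` is dominated by the larger storage modulus and barely
#' distinguishes models that differ mainly in the shape of the loss
#' modulus, so it ranks less reliably (see the methods vignette). A model
#' whose fit errors is dropped with a warning rather than aborting the
#' others.
#'
#' @inheritParams fit_sweep
#' @return A list of [fit_sweep()] results, best first, with class
#'   `model_comparison`.
#' @export
compare_models <- function(sweep, convention = "hz", multistart = FALSE) {
  fits <- list()
  for (m in model_ids) {
    res <- tryCatch(fit_sweep(sweep, m, convention, multistart),
                    error = function(e) {
                      warning("compare_models: ", conditionMessage(e),
                              call. = FALSE)
                      NULL
                    })
    if (!is.null(res)) fits[[m]] <- res
  }
  if (!length(fits)) stop("compare_models: all model fits failed",
                          call. = FALSE)
  ord <- order(vapply(fits, `[[`, numeric(1), "residual_norm"),
               -vapply(fits, `[[`, numeric(1), "r2"))
  structure(fits[ord], class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model ranking (best first):\n")
  for (ft in x)
    cat(sprintf("  %-4s r2 = %.5f  resid = %.4g\n", toupper(ft$model_id),
                ft$r2, ft$residual_norm))
  invisible(x)
}

#' Linear dependence of the springpot consistence on axial pre-strain
#'
#' Fits `K_alpha = k0 * (1 + b * eps_A)` by ordinary least squares of
#' `K_alpha` on the axial strain (a plain linear regression
#' `K = c0 + c1 * eps_A`, reparameterized as `k0 = c0`, `b = c1 / c0`).
#'
#' @param axial_strain Axial pre-strain values, percent; or a two-column
#'   data frame `(axial_strain, k_alpha)`.
#' @param k_alpha Fitted consistence at each strain, kPa.s^alpha. Omit when
#'   a data frame is given.
#' @return An object of class `strain_dependence`: `k0` (kPa.s^alpha at zero
#'   strain), `b` (per percent strain), `fit_r2`, `n`.
#' @examples
#' eps <- c(0.5, 2.5, 4.5, 6.5, 8.5, 10.5)
#' fit_strain_dependence(eps, 0.69 * (1 + 0.23 * eps))
#' @export
fit_strain_dependence <- function(axial_strain, k_alpha = NULL) {
  if (is.data.frame(axial_strain)) {
    k_alpha <- axial_strain[[2]]
    axial_strain <- axial_strain[[1]]
  }
  if (length(axial_strain) != length(k_alpha) || length(axial_strain) < 3)
    stop("fit_strain_dependence: need >= 3 (strain, K_alpha) pairs",
         call. = FALSE)
  fit <- stats::lm(k_alpha ~ axial_strain)
  co <- stats::coef(fit)
  k0 <- unname(co[1])
  if (k0 <= 0)
    stop("fit_strain_dependence: intercept k0 <= 0; data inconsistent with ",
         "K_alpha = k0 * (1 + b * strain)", call. = FALSE)
  ss_tot <- sum((k_alpha - mean(k_alpha))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(k0 = k0, b = unname(co[2]) / k0, fit_r2 = r2,
                 n = length(axial_strain)),
            class = "strain_dependence")
}

#' @export
print.strain_dependence <- function(x, ...) {
  cat(sprintf("K_alpha = k0 (1 + b eps_A): k0 = %.3f kPa.s^a, b = %.3f /%%, r2 = %.4f (n = %d)\n",
              x$k0, x$b, x$fit_r2, x$n))
  invisible(x)
}

#' Summary table of fitted springpot parameters by group
#'
#' Aggregates a list of springpot+dashpot fits into a per-group table of
#' mean and standard deviation for `K_alpha`, `alpha` and `eta`, with the
#' coefficient of variation of `K_alpha` (a measure of biological
#' variability between samples). Values are rounded half-up to 2 decimals at
#' this reporting boundary.
#'
#' @param fits List of `fit_result` objects from springpot+dashpot fits.
#' @param group Character vector of group labels (e.g. organ), one per fit.
#' @param digits Decimals for the rounded columns. Default 2.
#' @return A data frame, one row per group: n, mean and sd of each
#'   parameter, and `k_alpha_cv_pct`.
#' @export
make_parameter_table <- function(fits, group = rep("all", length(fits)),
                                 digits = 2) {
  if (!length(fits)) stop("make_parameter_table: no fits", call. = FALSE)
  stopifnot(length(group) == length(fits))
  grab <- function(field) vapply(fits, function(f) f$params[[field]],
                                 numeric(1))
  d <- data.frame(group = as.character(group), k_alpha = grab("k_alpha"),
                  alpha = grab("alpha"), eta = grab("eta"))
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  agg <- do.call(rbind, lapply(split(d, d$group), function(g) {
    data.frame(group = g$group[1], n = nrow(g),
               k_alpha_mean = mean(g$k_alpha), k_alpha_sd = sd0(g$k_alpha),
               alpha_mean = mean(g$alpha), alpha_sd = sd0(g$alpha),
               eta_mean = mean(g$eta), eta_sd = sd0(g$eta))
  }))
  agg$k_alpha_cv_pct <- ifelse(agg$k_alpha_mean > 0,
                               agg$k_alpha_sd / agg$k_alpha_mean * 100, 0)
  num <- vapply(agg, is.numeric, logical(1)) & names(agg) != "n"
  agg[num] <- lapply(agg[num], round_half_up, digits = digits)
  rownames(agg) <- NULL
  agg
}
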