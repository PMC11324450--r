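# Closed-form moduli, relaxation modulus, and the Grunwald-Letnikov oracle.

test_that("springpot+dashpot storage modulus matches published fit evaluations", {
  # values the fitted organ parameters produce at literature frequencies
  expect_equal(round_half_up(sfkv_complex_modulus(heart_params(), 80)$storage),
               3.46)
  expect_equal(round_half_up(sfkv_complex_modulus(kidney_params(), 300)$storage),
               1.71)
})

test_that("springpot+dashpot loss modulus carries the eta*f/1000 viscous term", {
  # frozen from direct high-precision evaluation:
  # 0.88*sin(0.06*pi) + 7.58/1000 at f = 1 Hz
  expect_equal(sfkv_complex_modulus(kidney_params(), 1)$loss, 0.1724756,
               tolerance = 1e-6)
  # eta contributes only to loss
  with_eta <- sfkv_complex_modulus(kidney_params(), 5)
  no_eta <- sfkv_complex_modulus(sfkv_params(0.88, 0.12, 0), 5)
  expect_equal(with_eta$storage, no_eta$storage)
  expect_equal(with_eta$loss - no_eta$loss, 7.58 * 5 / 1000)
})

test_that("degenerate fractional orders recover spring and dashpot", {
  f <- c(0.3, 1, 7)
  spring <- sfkv_complex_modulus(sfkv_params(1.7, 0, 0), f)
  expect_equal(spring$storage, rep(1.7, 3))
  expect_equal(spring$loss, rep(0, 3))
  dash <- fkv_complex_modulus(fkv_params(2.4, 1, 0), f)
  expect_equal(dash$storage, rep(0, 3), tolerance = 1e-12)
  expect_equal(dash$loss, 2.4 * f)
})

test_that("springpot+spring modulus matches hand evaluations", {
  cm <- fkv_complex_modulus(fkv_params(1, 0.5, 1), 1)
  expect_equal(cm$storage, 1 + cos(pi / 4))
  expect_equal(cm$loss, sin(pi / 4))
  flat <- fkv_complex_modulus(fkv_params(1e-12, 0.3, 5), c(0.1, 1, 10))
  expect_equal(flat$storage, rep(5, 3), tolerance = 1e-9)
})

test_that("standard linear solid matches hand evaluations and limits", {
  # eta chosen so f*tau = 1 at f = 1 Hz: tau = eta/1000/g2 = 1 s
  cm <- sls_complex_modulus(sls_params(1, 1, 1000), 1)
  expect_equal(cm$storage, 1.5)
  expect_equal(cm$loss, 0.5)
  expect_equal(sls_complex_modulus(sls_params(1, 1, 1000), 1e9)$storage, 2,
               tolerance = 1e-6)  # high-frequency plateau g1 + g2
  flat <- sls_complex_modulus(sls_params(2, 0, 0), c(0.5, 5))
  expect_equal(flat$storage, rep(2, 2))
  expect_equal(flat$loss, rep(0, 2))
  expect_error(sls_params(1, 0, 10), "series arm")
})

test_that("parameter constructors reject out-of-domain values", {
  expect_error(sfkv_params(-1, 0.1, 0), "k_alpha")
  expect_error(sfkv_params(1, 1.2, 0), "alpha")
  expect_error(sfkv_params(1, 0.1, -2), "eta")
  expect_error(sfkv_params(NaN, 0.1, 0), "finite")
  expect_error(sfkv_complex_modulus(kidney_params(), c(1, -2)), "> 0")
})

test_that("moduli are non-negative and S-FKV storage increases with frequency", {
  set.seed(42)
  f <- study_frequencies(10)
  for (i in 1:20) {
    for (m in c("sfkv", "fkv", "sls")) {
      cm <- complex_modulus(draw_params(m), f)
      expect_true(all(cm$storage >= 0) && all(cm$loss >= 0))
    }
    cm <- sfkv_complex_modulus(draw_params("sfkv"), f)
    expect_true(all(diff(cm$storage) > 0))
  }
})

test_that("zero fractional order collapses both fractional models to Kelvin-Voigt", {
  f <- study_frequencies(10)
  kv_sfkv <- sfkv_complex_modulus(sfkv_params(1.3, 0, 12), f)
  expect_equal(kv_sfkv$storage, rep(1.3, 10))
  expect_equal(kv_sfkv$loss, 12 * f / 1000)
  # springpot+spring with alpha = 1 is also Kelvin-Voigt (viscosity in kPa.s)
  kv_fkv <- fkv_complex_modulus(fkv_params(0.004, 1, 1.3), f)
  expect_equal(kv_fkv$storage, rep(1.3, 10), tolerance = 1e-12)
  expect_equal(kv_fkv$loss, 0.004 * f)
})

test_that("storage modulus obeys exact power-law frequency scaling", {
  p <- draw_params("sfkv")
  f1 <- c(0.2, 1.7, 40); f2 <- c(0.9, 3.1, 800)
  g1 <- sfkv_complex_modulus(p, f1)$storage
  g2 <- sfkv_complex_modulus(p, f2)$storage
  expect_equal(g1 / g2, (f1 / f2)^p$alpha, tolerance = 1e-14)
})

test_that("rad convention rescales the power law by (2*pi)^alpha", {
  p <- kidney_params()
  hz <- sfkv_complex_modulus(p, 5, convention = "hz")
  rad <- sfkv_complex_modulus(p, 5, convention = "rad")
  expect_equal(rad$storage / hz$storage, (2 * pi)^p$alpha)
})

test_that("relaxation modulus follows the power law with gamma-function prefactor", {
  p <- kidney_params()
  expect_equal(sfkv_relaxation_modulus(p, 1), 0.88 / gamma(0.88))
  expect_equal(sfkv_relaxation_modulus(sfkv_params(1.4, 0, 3), c(1, 5, 80)),
               rep(1.4, 3))
  h <- heart_params()
  expect_equal(sfkv_relaxation_modulus(h, 10),
               sfkv_relaxation_modulus(h, 1) / 10^0.13)
  g <- sfkv_relaxation_modulus(p, seq(1, 10, by = 0.5))
  expect_true(all(diff(g) < 0))
  expect_error(sfkv_relaxation_modulus(p, 0), "> 0")
  expect_error(sfkv_relaxation_modulus(p, c(1, -1)), "> 0")
})

test_that("GL stress response reduces to the integer-order laws", {
  # alpha = 0: sigma = K*eps + eta*deps/dt pointwise
  tt <- seq(0, 2, by = 0.01)
  hist <- strain_history(tt, 0.001 * sin(tt))
  p0 <- sfkv_params(1.5, 0, 8)
  st <- gl_stress_response(p0, hist, 0.01)
  eps <- 0.001 * sin(st$time)
  rate <- diff(c(0, 0.001 * sin(tt)))[-1] / 0.01
  expect_equal(st$stress, 1.5 * eps + 8 / 1000 * rate, tolerance = 1e-9)
  # alpha = 1, eta = 0, constant ramp rate r: sigma = K * r
  ramp <- strain_history(tt, 0.002 * tt)
  p1 <- sfkv_params(0.7, 1, 0)
  st1 <- gl_stress_response(p1, ramp, 0.01)
  expect_equal(st1$stress, rep(0.7 * 0.002, length(st1$stress)),
               tolerance = 1e-9)
})

test_that("GL step response converges to the closed-form relaxation modulus", {
  p <- kidney_params()
  st <- gl_stress_response(p, step_strain_history(0.001, 10, 0.001), 0.001)
  idx <- match(1:10, round(st$time, 9))
  expect_true(all(!is.na(idx)))
  err <- rel_err(st$stress[idx] / 0.001, sfkv_relaxation_modulus(p, 1:10))
  expect_lt(max(err), 0.02)
})

test_that("GL oracle refuses a dt coarser than the history resolution", {
  hist <- strain_history(seq(0, 1, by = 0.01), rep(0.001, 101))
  expect_error(gl_stress_response(kidney_params(), hist, 0.05), "dt exceeds")
})

test_that("strain histories are validated", {
  expect_error(strain_history(c(0, 1, 1), c(0, 0, 0)), "strictly increasing")
  expect_error(strain_history(c(0, 1), c(0, 0, 0)), "equal length")
})
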