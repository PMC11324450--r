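# Joint least-squares fitting, model comparison, strain-dependence law.

test_that("noiseless kidney sweep round-trips to the generating parameters", {
  ft <- fit_sweep(clean_sfkv_sweep(kidney_params()), "sfkv")
  expect_lt(max(rel_err(unlist(ft$params), unlist(kidney_params()))), 1e-6)
  expect_equal(ft$r2, 1, tolerance = 1e-10)
  expect_equal(ft$n_points, 20)
  expect_equal(ft$convention, "hz")
})

test_that("all three models round-trip noiselessly over random draws", {
  set.seed(11)
  f <- study_frequencies()
  for (i in 1:10) {
    for (m in c("sfkv", "fkv", "sls")) {
      p <- draw_params(m)
      cm <- complex_modulus(p, f)
      sw <- frequency_sweep(f, cm$storage, cm$loss)
      ft <- fit_sweep(sw, m)
      expect_lt(max(rel_err(unlist(ft$params), unlist(p))), 1e-6)
    }
  }
})

test_that("the optimizer beats a brute-force grid on a small instance", {
  set.seed(3)
  f <- c(0.1, 0.5, 1.5, 4, 9.5)
  sw <- gen_frequency_sweep(organ_profile("kidney"), n_points = 5,
                            f_range = c(0.1, 9.5), seed = 3)
  obs <- c(sw$storage, sw$loss)
  objective <- function(k, a, e) {
    cm <- sfkv_complex_modulus(sfkv_params(k, a, e), sw$frequency)
    sum(((c(cm$storage, cm$loss) - obs) / obs)^2)
  }
  grid <- expand.grid(k = seq(0.4, 1.6, length.out = 20),
                      a = seq(0.01, 0.4, length.out = 20),
                      e = seq(0, 30, length.out = 20))
  grid_min <- min(mapply(objective, grid$k, grid$a, grid$e))
  ft <- fit_sweep(sw, "sfkv")
  expect_lte(ft$residual_norm^2, grid_min)
})

test_that("fits on noisy sweeps keep r2 at the reported level", {
  prof <- organ_profile("kidney")
  for (s in 1:5) {
    sw <- gen_frequency_sweep(prof, n_points = 20, f_range = c(0.1, 9.5),
                              seed = s)
    expect_gte(fit_sweep(sw, "sfkv")$r2, 0.99)
  }
})

test_that("parameter recovery under 3% noise stays within 5% median error", {
  prof <- organ_profile("kidney")
  errs <- sapply(1:40, function(s) {
    ft <- fit_sweep(gen_frequency_sweep(prof, n_points = 20,
                                        f_range = c(0.1, 9.5), seed = s),
                    "sfkv")
    c(rel_err(ft$params$k_alpha, 0.88), rel_err(ft$params$alpha, 0.12))
  })
  expect_lt(median(errs[1, ]), 0.05)
  expect_lt(median(errs[2, ]), 0.05)
})

test_that("the generating model wins the comparison on model-true data", {
  sw <- gen_frequency_sweep(organ_profile("kidney"), n_points = 20,
                            f_range = c(0.1, 9.5), seed = 5)
  cmp <- compare_models(sw)
  expect_equal(cmp[[1]]$model_id, "sfkv")
  expect_equal(sort(unname(sapply(cmp, `[[`, "model_id"))),
               c("fkv", "sfkv", "sls"))
  # springpot+spring data has frequency-flat elastic storage and pure
  # power-law loss; the Zener model cannot reproduce that pair
  p <- fkv_params(0.3, 0.25, 1.2)
  cm <- fkv_complex_modulus(p, study_frequencies())
  set.seed(21)
  sw2 <- frequency_sweep(study_frequencies(),
                         cm$storage * exp(rnorm(20, 0, 0.02)),
                         cm$loss * exp(rnorm(20, 0, 0.02)))
  ranked <- sapply(compare_models(sw2), `[[`, "model_id")
  expect_lt(which(ranked == "fkv"), which(ranked == "sls"))
})

test_that("fit_sweep demands enough cleaned points", {
  sw <- clean_sfkv_sweep(kidney_params(), c(0.5, 1, 2, 4))
  expect_error(fit_sweep(sw, "sfkv"), "at least 5")
})

test_that("strain-dependence law is recovered exactly from exact data", {
  eps <- c(0.5, 2.5, 4.5, 6.5, 8.5, 10.5)
  sd_fit <- fit_strain_dependence(eps, 0.69 * (1 + 0.23 * eps))
  expect_equal(sd_fit$k0, 0.69, tolerance = 1e-12)
  expect_equal(sd_fit$b, 0.23, tolerance = 1e-12)
  expect_equal(sd_fit$fit_r2, 1)
  flat <- fit_strain_dependence(eps, rep(0.5, 6))
  expect_equal(flat$b, 0, tolerance = 1e-12)
  expect_error(fit_strain_dependence(c(1, 2), c(1, 2)), ">= 3")
  # data-frame input matches vector input
  df_fit <- fit_strain_dependence(data.frame(eps, k = 0.69 * (1 + 0.23 * eps)))
  expect_equal(df_fit$b, sd_fit$b)
})

test_that("parameter table aggregates fits with mean, sd and cv", {
  sw <- clean_sfkv_sweep(kidney_params())
  ft <- fit_sweep(sw, "sfkv")
  single <- make_parameter_table(list(ft))
  expect_equal(single$k_alpha_mean, 0.88)
  expect_equal(single$k_alpha_sd, 0)
  expect_equal(single$n, 1)
  # two synthetic samples with known spread: sd/mean ratio is reported
  fits <- list(ft, ft)
  fits[[2]]$params$k_alpha <- 0.88 * 1.5
  tab <- make_parameter_table(fits, group = c("kidney", "kidney"))
  expect_equal(tab$k_alpha_mean, round_half_up(0.88 * 1.25, 2))
  expect_equal(tab$k_alpha_cv_pct,
               round_half_up(sd(c(0.88, 1.32)) / 1.1 * 100, 2))
  dup <- make_parameter_table(list(ft, ft))
  expect_equal(dup$k_alpha_sd, 0)
})
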