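# Shared fixtures: reference organ parameters and small utilities.

kidney_params <- function() sfkv_params(k_alpha = 0.88, alpha = 0.12, eta = 7.58)
heart_params <- function() sfkv_params(k_alpha = 2.00, alpha = 0.13, eta = 10.3)

study_frequencies <- function(n = 20, lo = 0.1, hi = 9.5)
  exp(seq(log(lo), log(hi), length.out = n))

rel_err <- function(x, ref) abs(x / ref - 1)

# noiseless sweep from given springpot parameters
clean_sfkv_sweep <- function(params, f = study_frequencies()) {
  cm <- sfkv_complex_modulus(params, f)
  frequency_sweep(f, cm$storage, cm$loss)
}

# random parameter draws inside physiological ranges, one draw per call
draw_params <- function(model) {
  switch(model,
    sfkv = sfkv_params(runif(1, 0.1, 3), runif(1, 0.05, 0.3), runif(1, 2, 30)),
    fkv = fkv_params(runif(1, 0.05, 1), runif(1, 0.05, 0.5), runif(1, 0.1, 3)),
    sls = {
      g2 <- runif(1, 0.1, 3)
      tau <- exp(runif(1, log(0.2), log(2)))
      sls_params(runif(1, 0.1, 3), g2, tau * g2 * 1000)
    })
}
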