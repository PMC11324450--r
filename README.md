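# rheofrac

Fractional viscoelastic analysis of soft-tissue oscillatory shear
rheometry.

Soft organs — heart, kidney, liver, brain — show power-law viscoelasticity:
over the usable rheometer band (0.1 Hz up to an inertia-limited cutoff near
10 Hz) both the storage modulus G′ and the loss modulus G″ grow as
fractional powers of frequency. `rheofrac` is for experimentalists and
modellers who need to turn such sweeps into material parameters and
predictions: it fits three-parameter viscoelastic models to frequency
sweeps, detects the data-quality limits that precede any fit, and uses the
fitted model to predict stress relaxation in time and shear stiffness at
elastography frequencies far above the measured band.

## The model

The core element is the springpot (Scott–Blair element),
σ = K<sub>α</sub> d<sup>α</sup>ε/dt<sup>α</sup>, which interpolates between
a spring (α = 0) and a dashpot (α = 1). The working model is a springpot in
parallel with a dashpot:

    G'(f)  = K_a f^a cos(a*pi/2)
    G''(f) = K_a f^a sin(a*pi/2) + eta*f
    G(t)   = eta*delta(t) + K_a t^(-a) / Gamma(1 - a)     (step-strain response)

with K<sub>α</sub> in kPa·s<sup>α</sup>, η in Pa·s, and f the ordinary
frequency in Hz (the convention under which the reference organ parameters
reproduce their published extrapolations; a `"rad"` flag is available).
Two rival three-parameter models — springpot + spring, and the standard
linear solid — are fitted alongside for model comparison. A
Grünwald–Letnikov discretization provides an independent numerical oracle
for the time-domain law.

## Worked example

Simulate a kidney-like frequency sweep (springpot parameters
K<sub>α</sub> = 0.88 kPa·s<sup>α</sup>, α = 0.12, η = 7.58 Pa·s, 3%
multiplicative noise), fit and rank the three models, and extrapolate:

```r
library(rheofrac)
prof <- organ_profile("kidney")
sw   <- gen_frequency_sweep(prof, n_points = 20, f_range = c(0.1, 9.5), seed = 1)

fit <- fit_sweep(sw, "sfkv")
#> Model SFKV fit (20 points, hz convention): r2 = 0.9978
#> <sfkv_params> k_alpha = 0.882857, alpha = 0.118804, eta = 8.09312

compare_models(sw)
#> Model ranking (best first):
#>   SFKV r2 = 0.99778  resid = 0.1657
#>   FKV  r2 = 0.99742  resid = 0.2491
#>   SLS  r2 = 0.95492  resid = 1.958

extrapolate_storage(fit$params, c(75, 300), range = TRUE)
#>   frequency  storage rounded
#> 1        75 1.448931    1.45
#> 2       300 1.708342    1.71
```

The fit recovers the generating parameters to about 1% and identifies the
generating model; the extrapolated 1.45–1.71 kPa band is the shear
stiffness this specimen would present to magnetic-resonance elastography at
75–300 Hz. The same fitted parameters predict time-domain relaxation, here
against a trace whose amplitude was biased 29% high to emulate the
frequency-vs-time-domain mismatch seen in practice:

```r
meas <- gen_relaxation_trace(prof, bias = 1.29, seed = 2)
compare_relaxation(predict_relaxation(fit$params, 1:10), meas)
#> Relaxation comparison over t = 1..10 s:
#>   initial (t = 1 s) discrepancy: -20.0% (predicted vs measured)
#>   decay-shape distance: 8.04%
```

The comparison separates an amplitude offset (−20% at 1 s) from the decay
shape, which the power law captures to within the noise. Preprocessing
helpers cover the steps before fitting: `detect_lve_limit` finds the strain
plateau (0.1% for these organs), `truncate_inertial` masks the
high-frequency inertial dip, and `contact_axial_state` converts the 0.1 N
plate contact force into the axial pre-strain (≈200 Pa → 0.5% at
E = 44 kPa).

A command-line wrapper for the same pipeline is in `inst/cli/rheofrac`
(subcommands `fit-sweep`, `compare-models`, `extrapolate`, `simulate`,
`reproduce-tables`, …).

## Documentation

The methods vignette (`vignettes/fractional-viscoelasticity.Rmd`) documents
the models and their assumptions, the frequency-unit convention, the
fitting objective and model-ranking statistic, the preprocessing
tolerances, what the synthetic generator does and does not emulate, and the
package's numerical choices.
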