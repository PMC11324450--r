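---
title: "Fractional viscoelastic analysis of soft-tissue rheometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractional viscoelastic analysis of soft-tissue rheometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rheofrac)
```

## The problem

Soft organs (heart, kidney, liver, brain) loaded in oscillatory shear show
power-law frequency dependence of both the storage modulus $G'$ and the loss
modulus $G''$ over the sub-10 Hz band a plate rheometer can reach before
instrument inertia corrupts the signal. Classical spring--dashpot networks
with few elements cannot produce a power law; fractional-order elements can.
This package fits such measurements with three-parameter viscoelastic
models, checks the data-quality limits that precede any fit (linear
viscoelastic range, inertial bandwidth), and uses the fitted model to
predict behaviour the fit never saw: time-domain stress relaxation and the
storage modulus at elastography frequencies far above the measured band.

## Models

The central element is the **springpot** (Scott--Blair element), whose
stress is proportional to the fractional derivative of strain,
$\sigma = K_\alpha\, d^\alpha \varepsilon / dt^\alpha$. $K_\alpha$ (the
*coefficient of consistence*, kPa\,s$^\alpha$) and the order
$\alpha \in [0,1]$ interpolate continuously between a spring
($\alpha = 0$) and a dashpot ($\alpha = 1$). Three parallel networks are
supported, each with three parameters:

* **springpot + dashpot** (`sfkv_params`): the working model.
  $G' = K_\alpha \omega^\alpha \cos(\alpha\pi/2)$,
  $G'' = K_\alpha \omega^\alpha \sin(\alpha\pi/2) + \eta\omega$.
* **springpot + spring** (`fkv_params`):
  $G' = K_\alpha \omega^\alpha \cos(\alpha\pi/2) + G$,
  $G'' = K_\alpha \omega^\alpha \sin(\alpha\pi/2)$.
* **standard linear solid** (`sls_params`): the Zener form with
  $\tau = \eta/G_2$:
  $G' = G_1 + G_2 (\omega\tau)^2/(1 + (\omega\tau)^2)$,
  $G'' = G_2 \omega\tau/(1 + (\omega\tau)^2)$.

The springpot + dashpot model's response to a step strain
$\varepsilon_0 H(t)$ is the relaxation modulus

$$G(t) = \eta\,\delta(t) + \frac{K_\alpha\, t^{-\alpha}}{\Gamma(1-\alpha)},$$

a pure power-law decay for $t > 0$. The $\delta(t)$ impulse is carried by
the dashpot exactly at $t = 0$; numerical evaluation therefore starts at
$t > 0$, and comparisons against measured traces start at 1 s, the first
sample of the standard relaxation protocol (1 s sampling for 10 s).

### The frequency convention

The power laws above are stated in terms of a frequency variable
$\omega$. This package evaluates them by default with $\omega$ taken as the
**ordinary frequency $f$ in Hz**, not the angular frequency $2\pi f$: the
reference parameter sets for the four organs reproduce the published
extrapolated moduli exactly under the Hz convention (e.g. heart,
$2.00 \cdot 80^{0.13}\cos(0.13\pi/2) = 3.46$ kPa at 80 Hz) and not under
rad/s. The same $K_\alpha$ also enters the time-domain law with $t$ in
seconds; the pair of conventions is kept exactly as the parameters were
fitted rather than "corrected", because re-deriving one convention from the
other would silently rescale $K_\alpha$ by $(2\pi)^{\pm\alpha}$ (about 25%
at $\alpha = 0.12$). Every fit result and report records the flag, and
`convention = "rad"` is available throughout.

Units: moduli and $K_\alpha$ are carried in kPa, viscosities in Pa\,s, so
the viscous loss term is $\eta f / 1000$ kPa. Files on disk carry Pa (the
instrument scale); containers convert at the boundary.

## Preprocessing

**LVE limit** (`detect_lve_limit`). The plateau reference is the mean $G'$
of the three smallest amplitudes; the limit is the largest amplitude below
which every $G'$ stays within a relative `tolerance` of that reference.
The default tolerance is 5%: plateau identification in practice is done by
eye on a log axis, and 5% is about the smallest departure visible there
while staying above rheometer repeatability (~3%). Only $G'$ is used — it
dominates the signal and is less noisy than $G''$. The four-organ study
places this limit at 0.1% shear strain.

**Inertial cutoff** (`detect_inertial_cutoff`). Instrument inertia appears
as a dip in $G'$ (and rise in $G''$) at high frequency. The cutoff is the
lowest frequency whose $G'$ falls more than `drop_tolerance` (default 5%,
same reasoning) below its running maximum; the cutoff point itself and
everything above are excluded from fitting. The first dipping point is
excluded rather than kept, the conservative choice when the artifact's
onset is only known to one grid point.

**Contact conversion** (`contact_axial_state`). The 0.1 N contact force on
a 25 mm disc gives an axial stress of $F/(\pi r^2) = 203.7$ Pa; by default
the stress is rounded to the nearest 100 Pa (200 Pa) before dividing by the
elastic modulus, because the reported per-organ strains (0.2, 0.5, 1.1,
13.3% for E = 110, 44, 17.5, 1.5 kPa) all follow exactly from the 200 Pa
working figure. `round_stress = FALSE` gives the exact-area value.

## Fitting

`fit_sweep` minimizes the summed squared **relative** residuals of $G'$ and
$G''$ jointly, with box constraints ($0 \le \alpha \le 1$, other parameters
$\ge 0$) via the Levenberg--Marquardt implementation in `minpack.lm`.
Relative weighting is the material decision: $G''$ is typically 4--6 times
smaller than $G'$, and absolute least squares would let the storage channel
dictate every parameter, including $\eta$, which only the loss channel
constrains. Starting values are deterministic — $\alpha_0$ from the
log--log slope of the relevant channel, $K_{\alpha,0}$ from its level,
$\eta_0$ or the spring moduli from endpoint residuals — so a fit is a pure
function of its data; `multistart = TRUE` adds a fixed grid of extra starts
for pathological data.

Two goodness statistics are reported and play different roles:

* `r2`, the coefficient of determination $1 - SS_{res}/SS_{tot}$ over the
  concatenated raw (kPa) $(G', G'')$ vector — the $R^2$ a joint
  least-squares fit conventionally reports, and the scale on which sweeps
  of these organs fit better than 0.99. A per-channel-normalized variant
  was considered and rejected: under the study's own noise level (3%
  multiplicative), even the *generating* curve scores only ~0.98 on the
  normalized statistic, so it cannot be the scale on which fits better
  than 0.99 were reported.
* `residual_norm`, the root of the minimized objective. `compare_models`
  ranks models by this, not by `r2`: the raw-kPa `r2` is dominated by the
  storage channel and nearly blind to the loss channel, where the
  springpot-plus-dashpot vs springpot-plus-spring distinction lives. In
  simulation (kidney parameters, 3% noise, 100 seeds) objective ranking
  identifies the generating model in 100/100 runs; `r2` ranking in only
  87/100.

`fit_strain_dependence` fits the observed linear stiffening of the
consistence with axial pre-strain, $K_\alpha = k_0(1 + b\,\varepsilon_A)$,
as an ordinary linear regression reparameterized at the end
($k_0 = c_0$, $b = c_1/c_0$); uncertainty quoted on such parameters in
reports is across-sample spread, not the regression's own interval.

## Relaxation analysis

`predict_relaxation` evaluates the power-law relaxation modulus from
frequency-domain parameters. `compare_relaxation` splits the disagreement
with a measured trace into two numbers: the signed initial discrepancy
$(\text{pred} - \text{meas})/\text{meas} \times 100$ at the earliest common
time (so "predicted 29% less" reads $-29$), and the decay-shape distance,
the maximum relative deviation after both curves are divided by their own
initial value — identically zero when the curves differ only by a constant
amplitude factor, which is the empirically observed failure mode.

`extrapolate_storage` evaluates $G'$ at arbitrary frequencies; band
summaries report the two endpoint values (the power law is monotone, so
endpoints bound the band), rounded half away from zero to 2 decimals for
table parity.

## The Grünwald–Letnikov oracle

`gl_stress_response` is an independent numerical route to the same
constitutive law: the fractional derivative is discretized with first-order
Grünwald--Letnikov weights $w_0 = 1$, $w_j = w_{j-1}(j - 1 - \alpha)/j$
over the full memory (no short-memory truncation — traces here are
$\le 10^4$ steps, and the convolution is evaluated by FFT, so the cost is
irrelevant), and the dashpot by a backward difference. For a step strain at
$dt = 1$ ms the normalized stress matches the closed-form relaxation
modulus within 2% over 1--10 s for all four organ parameter sets; this
cross-check is in the test suite. The gamma function is R's `gamma()`
(Lanczos-class accuracy); no bespoke approximation.

## Synthetic data

`organ_profile` carries, per organ, the reference springpot parameters, the
$K_\alpha(\varepsilon_A)$ law $(k_0, b)$, a per-strain drift table for
$\alpha$ and $\eta$, the LVE limit (0.1%), the inertial onset (9.5 Hz heart
and kidney, 4.2 Hz liver, 2.8 Hz brain), the measurement noise level and
the elastic modulus. The generators emulate exactly the statistical
structure the analysis assumes:

* **Noise** is multiplicative lognormal with unit mean and a single
  coefficient-of-variation knob, default 3% — rheometer moduli errors are
  scale-proportional, and 3% reproduces the fit quality (r² ≳ 0.99) seen
  on real sweeps of this kind. No per-frequency correlation is modelled.
* **Inertial artifact**: strictly above the onset, $G'$ is multiplied by
  $1/(1 + (f/f_{onset})^4)$ and $G''$ gains a term growing as $f^2$. The
  shape mimics the look of inertia-limited sweeps; it is not a physical
  model of plate inertia. The onset frequency is inserted into the grid so
  the artifact's first point is well defined.
* **Amplitude softening**: above the LVE limit both moduli follow a
  Kraus-type decay $1/(1 + (\gamma/\gamma_c)^m)$, $m = 0.8$, with
  $\gamma_c$ placed so the departure from the plateau reaches the
  detector's tolerance exactly at the limit — the generated limit is then
  recoverable to within one grid point, which is all an amplitude grid can
  promise.
* **Relaxation traces** are the closed-form power law times noise, with an
  optional constant `bias` factor emulating the up-to-30% initial-amplitude
  mismatch observed between frequency-domain predictions and measured
  relaxation.

Passing tests on these data show the pipeline recovers the structure it
assumes, at the noise level it assumes; they do not show robustness to
slip, sample-to-sample covariance, temperature drift (<10% between 20 and
37 °C, not modelled) or non-power-law tissue behaviour outside the fitted
band.

## Numerical choices and degenerate inputs

* Optimizer tolerances `ftol = ptol = 1e-15`, 500 iterations: noiseless
  round-trips recover parameters to ~$10^{-10}$ relative, comfortably
  inside the $10^{-6}$ the tests assert.
* Relative residuals divide by `pmax(obs, 1e-6 * max(obs))`, so a zero
  loss channel (purely elastic data) cannot produce infinite weights;
  constant-moduli sweeps warn and may return boundary solutions.
* Parameters that land on a box bound are listed in the fit result's
  `boundary` field rather than silently accepted.
* Reporting rounds half away from zero (`round_half_up`), since base R's
  half-to-even would disagree with printed tables on exact halves.
* Problem sizes used in the simulation-based tests: 20 frequencies per
  sweep, 100 seeds per stochastic claim, 6 pre-strain levels for the
  strain-dependence recovery, $10^4$-step traces for the oracle check.

## Limitations

Creep compliance, arbitrary fractional networks, Prony-series fits,
time-domain fitting, physical inertia correction (only truncation), and
nonlinear constitutive response within a single evaluation are all out of
scope. The axial-strain dependence is handled by refitting per strain level
and regressing the consistence; $\alpha$ and $\eta$ drift with pre-strain
is available in the generator's drift table but is not itself modelled.

```{r example}
# end-to-end on synthetic kidney data
prof <- organ_profile("kidney")
sw <- gen_frequency_sweep(prof, n_points = 20, f_range = c(0.1, 9.5), seed = 1)
compare_models(sw)
predict_relaxation(fit_sweep(sw, "sfkv")$params, 1:10)
```
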