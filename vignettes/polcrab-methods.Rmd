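---
title: "Models and methods in polcrab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in polcrab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polcrab)
```

`polcrab` implements the computational side of a polarization-vision
playback experiment: hermit crabs tethered in front of a modified LCD
screen are shown expanding-disc ("looming") stimuli that differ from the
background either in intensity or purely in degree of linear polarization
(DoP), and their startle responses are analysed psychometrically and with
mixed-effects logistic models. The package also converts
division-of-focal-plane (DoFP) polarization-camera images into Stokes
parameter maps for characterising the animals' visual habitat. This
vignette describes the models, the tunable parameters, the numerical
choices, and what the synthetic-data generator does and does not emulate.

## Stokes polarimetry from DoFP mosaics

A DoFP sensor carries micro-polarizers at 0°, 45°, 90° and 135° on the
four subpixels of each 2×2 superpixel. `demosaic()` splits a mosaic into
the four polarizer-angle images using non-overlapping superpixels — each
output pixel is one superpixel, at half the sensor resolution. We chose
this over sliding-window interpolation because it is the simplest scheme
in which every output pixel is an independent measurement; interpolating
demosaickers trade that independence for resolution and are out of scope.

`compute_stokes()` uses the pairwise-difference convention

$$S_0 = \tfrac{1}{2}(I_0 + I_{45} + I_{90} + I_{135}), \qquad
  S_1 = I_0 - I_{90}, \qquad S_2 = I_{45} - I_{135},$$

which makes $S_0$ equal to the scene intensity under ideal polarizers
(half-transmission of unpolarized light) and is exactly inverse to the
Malus-law forward model
$I_\phi = \tfrac{1}{2}(S_0 + S_1\cos 2\phi + S_2\sin 2\phi)$ used by the
synthetic renderer. A least-squares solution over the four redundant
angles would differ only in its noise weighting; for ideal noiseless
subpixels the two coincide, and the pairwise form is the standard
convention for this sensor family.

From the Stokes image, `dop_aop()` computes
$\mathrm{DoP} = \sqrt{S_1^2 + S_2^2}/S_0$ and
$\mathrm{AoP} = \tfrac{1}{2}\operatorname{atan2}(S_2, S_1)$, the latter in
degrees wrapped to $[-90, 90)$ with 0° horizontal. Numerical conventions:

* **DoP > 1.** Noise can push the polarized magnitude above $S_0$. Values
  are clipped to 1 and the number of clipped pixels is recorded in the
  `n_clipped` attribute.
* **AoP at DoP = 0.** $\operatorname{atan2}(0,0)$ is undefined; such
  pixels report 0° by convention, and pixels with DoP < 0.01 should be
  excluded from AoP summaries.
* **Exposure mask.** A superpixel is *overexposed* when any of its four
  subpixels reaches full scale minus `saturation_margin` (default 0:
  only true full-scale counts), and *underexposed* when
  $S_0 \le$ `floor_threshold` (default 1 count). Masking is
  per-superpixel, since a single saturated subpixel already corrupts all
  three Stokes components of that superpixel. False-colour renderings
  paint overexposed pixels white and underexposed pixels black in the DoP
  and AoP channels; the AoP colormap is a cyclic hue wheel so −90° and
  +90° meet without a seam.

Polarizer non-ideality (diattenuation, crosstalk between neighbouring
subpixels) is not modelled; no calibration matrix is applied.

## Looming stimuli

`angular_size()` gives the visual angle $2\arctan(d/2D)$ of a disc of
diameter $d$ at distance $D$; the reference stimulus (12 cm disc at
35 cm) subtends about 19° fully expanded. `expansion_profile()` supports
two interpretations of a geometrically expanding disc:

* **Constant approach** (default):
  $\theta(t) = 2\arctan\!\big(R/(v(t_{end}+\varepsilon-t))\big)$, the
  angular profile of a real object of radius $R$ closing at constant
  speed; $v$ and $\varepsilon$ are solved from the start and end angles.
  This form cannot start from exactly 0° in finite time, so expansion
  starts from a small configurable angle (default 0.5°).
* **Exponential**: $\theta(t) = \theta_{max} k^{t-T}$, constant
  multiplicative growth per unit time.

Both satisfy the same boundary conditions and hold the full-size disc for
`hold_duration` (default 2 s) before disappearing. Presets follow the
behavioural assay: 3 s expansion for terrestrial species, 10 s for the
marine species, 60 Hz frame rate. Neither form is asserted to be the
original stimulus generator's; both are provided and tested against
independent geometric simulations.

Contrast is parameterised as Weber contrast
$(I_{obj}-I_{bg})/I_{bg}$ for intensity stimuli (background at grey 158,
near the middle of the measured radiance range) and as the DoP difference
(stimulus − background) for polarization stimuli (background 50 %
polarized, horizontal). `screen_calibration()` holds the measured
grey-to-radiance and grey-to-DoP tables (piecewise linear, isotonically
regularised so the forward map is invertible) and `grey_for_target()`
inverts them to find the foreground grey for a requested contrast,
refusing targets outside the gamut. An identity calibration ships for
simulation; measured tables load from CSV (`grey,radiance,dop`).
`generate_series()` produces the randomized presentation series: a seeded
uniform shuffle of the contrast set with inter-trial intervals uniform on
[60, 180] s (the "1–3 min" design read as a uniform distribution), one
modality per series.

## Behavioural models

**Scoring and exclusion.** A trial counts as a response if any scored
behaviour (*stop*, *retreat*, *walk*) starts inside the scoring window.
The window is not dictated by the assay description, so the default spans
the whole stimulus — loom onset to end of hold (5 s terrestrial, 12 s
marine) — and is configurable. Trials with a full retreat before stimulus
onset are excluded (`apply_exclusions()`), the only exclusion rule.

**Psychometric curve.** `fit_sigmoid()` fits the 4-parameter logistic

$$p(x) = \text{bottom} + \frac{\text{top}-\text{bottom}}
  {1 + 10^{(x_{50}-x)\,\text{slope}}}$$

to per-contrast response proportions by weighted least squares (weights =
trials per proportion, the binomial information weight; an unweighted
option exists). The base-10 slope matches the convention of the
psychometric-fitting scripts common in this assay literature. Bounds keep
the asymptotes in $[0,1]$ and $x_{50}$ inside the tested contrast range;
$x_{50}$ is the half-maximum threshold. Fitting proportions rather than
raw binary trials reflects how such curves are conventionally fitted in
this assay; with equal trials per level the two give identical least
squares estimates. Two flags qualify the fit: `converged` reports
optimizer success only, while `on_boundary` marks estimates pinned at a
constraint — a curve whose true asymptotes are 0 and 1 legitimately sits
on the boundary, so boundary contact alone is not treated as failure.
`x50_reliable` is false for flat curves or thresholds at the edge of the
tested range. Fewer than four distinct contrast levels is an error (four
free parameters), mirroring the "where possible" caveat in this assay's
reporting. `sigmoid_boot_ci()` gives a percentile bootstrap interval for
$x_{50}$; the default is the model-based (parametric binomial) bootstrap,
which resamples per-level response counts from the fitted curve. A
nonparametric alternative resamples animals, the independent sampling
unit — it makes no model assumption and is the right choice when
between-animal heterogeneity matters, but in our calibration experiments
it undercovers slightly (about 0.90 empirical coverage for a nominal 0.95
interval at 20 animals), a known small-sample property of percentile
intervals for nonlinear functionals, whereas the parametric scheme is
calibrated at this design.

**Habituation.** `fit_habituation()` regresses mean response probability
on presentation order; the slope $h$ is the habituation rate (change in
response probability per trial). Responses are pooled across contrasts at
each order, since each animal sees every contrast exactly once in
randomized order.

**Mixed-effects logistic regression.** `fit_glmm()` fits
$\operatorname{logit} p = \beta_0 + \beta_c\,\text{contrast} +
\beta_o\,\text{order} + b_i$, $b_i \sim N(0,\sigma^2)$ per animal, by
maximum likelihood via adaptive Gauss–Hermite quadrature (20 nodes by
default; `nagq = 1` is the Laplace approximation, used in large
simulation loops). Contrast and order enter untransformed; an optional
squared centred-contrast term handles curvature where residual
diagnostics demand it. A singular fit ($\hat\sigma = 0$) is reported as a
valid boundary estimate, not a convergence failure. Effects are tested
with likelihood-ratio tests (`lrt()`): $\chi^2 = 2\Delta\ell$ against the
$\chi^2$ distribution with df equal to the parameter difference; p-values
are reported raw, without multiplicity correction.
`glmm_loglik_bruteforce()` recomputes the marginal log-likelihood by
direct numerical integration of the random intercept, an independent
check on the quadrature (the test suite requires agreement to $10^{-4}$;
at 25 nodes the observed gap on the toy dataset is below $10^{-10}$,
while the Laplace approximation differs at the $10^{-2}$ level — the
check genuinely discriminates).

**Polarity splits.** Response curves in this assay can be nearly
symmetric about the zero-contrast control, making a pooled *linear*
contrast term uninformative (the two arms cancel). `polarity_split_fits()`
fits the contrast model separately on the positive and negative subsets,
with the control trials included in both so each split retains an anchor
at zero — a deliberate choice; the alternative (controls in neither)
leaves the splits unanchored and was rejected.

## The synthetic-data generator

`simulate_trials()` draws trial tables from a psychometric observer
population: response probability is a 4-parameter sigmoid of *absolute*
contrast with separate half-maxima per polarity (allowing the asymmetric
curves this assay produces), each animal has a Gaussian logit-scale
intercept offset, and habituation subtracts a fixed probability per
successive trial. The additive-probability habituation matches the
line-fit definition of $h$, so recovery tests compare like with like —
a logit-scale decrement would make the "true" $h$ depend on the operating
point. Defaults mirror the experimental design: background DoP 0.5,
contrasts spanning −0.5…+0.5, one series per animal.
`simulate_logit_trials()` is the complementary generator matched to the
GLMM analysis (linear logit effect), used for calibration and power
studies. `render_mosaic()` renders Stokes scenes to quantized DoFP
mosaics with optional Gaussian read noise (photon shot noise is not
modelled; no noise characterisation of the real camera is available).

What the generator does **not** emulate: onset-time structure of the
three behaviours (responses are binary with a nominal onset), polarization
"noise" from real vegetation-rich scenes, screen non-uniformity, and any
dependence of habituation on contrast. Passing recovery tests therefore
demonstrates correctness of the estimators under the assumed statistical
structure, not robustness to every feature of real data.

## Reference study conditions

The validation studies (exported as `study_*()` functions, shared by the
test suite and `scripts/acceptance.R`) use these fixed conditions:

* **Polarimetry round trip**: 100 random uniform scenes of 8×8
  superpixels, $S_0 \sim U(3600, 4080)$ counts, DoP $\sim U(0.05, 1)$,
  AoP $\sim U(-90°, 90°)$, noiseless 12-bit rendering. The intensity
  range is the bright-but-unsaturated regime: a worst-case rounding
  analysis shows integer quantization alone can exceed a 2-count DoP
  tolerance for dim scenes, so the tolerance implies this exposure; the
  DoP floor keeps AoP defined everywhere.
* **Psychometric recovery**: 500 experiments of 20 animals × 9 contrasts
  (0.05–0.45), true curve bottom 0, top 1, $x_{50} = 0.20$, slope 8, no
  animal heterogeneity — a pure binomial observer, matching the model
  behind the parametric bootstrap (percentile, 199 resamples).
* **LRT calibration**: 1000 null replicates (no contrast effect,
  animal SD 0.5) and 200 alternative replicates at the reference effect
  size $\operatorname{logit} p = -1 + 4\,\text{contrast}$, 20 animals ×
  9 contrasts, Laplace fits.
* **Habituation recovery**: 500 replicates of 15 animals × 9 contrasts
  with a true 0.05 per-trial decrement; observer asymptotes (0.55–0.95)
  and animal SD (0.2) chosen so probabilities never clip at 0 or 1,
  which would bias the slope.

These sizes were chosen as the smallest designs at which the estimators'
sampling error is well inside the properties being checked.

## Known limitations

* The polarimetry stage assumes ideal polarizers and co-registered
  subpixels; real DoFP sensors need a per-pixel calibration matrix for
  quantitative field work.
* The exact functional form of the original expanding-disc profile is
  not recoverable from the assay description; both implemented forms are
  plausible readings.
* Exact third-decimal agreement with other GLMM implementations is not
  guaranteed — marginal likelihoods depend on the integration rule — so
  cross-software comparisons should be tolerance-bounded.
* The measured screen-calibration curves of the original apparatus are
  not public; the identity calibration is a synthetic stand-in and real
  tables should be supplied as CSV.
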