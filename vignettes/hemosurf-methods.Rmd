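---
title: "Methods: haemodynamic quantification, quadrant phenotyping and response-surface inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haemodynamic quantification, quadrant phenotyping and response-surface inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemosurf)
```

# The scientific problem

Two global haemodynamic markers summarise how an ageing brain balances
oxygen supply and demand. The **oxygen extraction fraction** (OEF) is the
fraction of arterial oxygen removed by tissue as blood transits the
capillary bed; by Fick's principle,

$$\mathrm{OEF} = \frac{Y_a - Y_v}{Y_a} \times 100\%,$$

where $Y_a$ and $Y_v$ are arterial and venous haemoglobin oxygen
saturation. **Global cerebral blood flow** (CBF) is total arterial inflow
normalised to brain mass (ml/100g/min). Their joint configuration is
informative: low CBF with compensatory high OEF — *misery perfusion* — marks
tissue running near the limit of its vascular reserve, while low OEF with
low CBF suggests metabolic down-regulation. This package implements the
full analysis chain from raw acquisition-level signals to cohort-level
inference: signal quantification, derived-variable construction,
quadrant phenotyping, covariate-adjusted association models, and
response-surface analysis (RSA) of the joint OEF/CBF dependence of white
matter hyperintensity (WMH) burden and cognition, together with a
synthetic-cohort generator that makes every stage testable without
subject-level data.

# Signal quantification

## Blood T2 from TRUST decay series

T2-relaxation-under-spin-tagging (TRUST) MRI isolates venous blood in the
superior sagittal sinus; its signal decays mono-exponentially across the
effective echo times (eTEs) of the T2 preparation, by default
0.44, 40, 80 and 160 ms:

$$S(\mathrm{eTE}) = S_0\, e^{-\mathrm{eTE}/T_2}.$$

`fit_blood_t2()` estimates $(S_0, T_2)$ by nonlinear least squares: a
log-linear regression of $\log S$ on eTE supplies starting values, refined
by Levenberg–Marquardt iterations to a relative tolerance of $10^{-10}$.
Degenerate inputs are handled explicitly: a non-negative log-space slope
or a fitted $T_2 > 10^4$ ms raises a fit error (a non-decaying series
carries no $T_2$ information), and series containing non-positive signals
— possible at deep decay under noise — bypass the log-linear initialiser,
start from $S_0 = \max S$, $T_2$ = half the eTE span, and are flagged.

A practical note on calibration checks: least-squares estimators of
exponential time constants carry a small second-order bias, of order the
squared noise-to-signal ratio. At 1% amplitude noise on the four-point
protocol this is below 0.1 ms — negligible against the ~1.4 ms replicate
SD and far inside the 1 ms bound the test suite enforces — but it is
intrinsic to the estimator, so the suite pins the bias bound and the
replicate dispersion rather than asserting exact unbiasedness.

## Calibration to venous oxygenation

Blood $T_2$ maps to venous oxygenation $Y_v$ through the quadratic
relaxivity law of the published TRUST calibration,

$$1/T_2 = a + b\,(1 - Y) + c\,(1 - Y)^2,$$

with coefficients $(a, b, c)$ evaluated at the subject's haematocrit via
the standard haematocrit polynomials (CPMG inter-echo spacing 10 ms,
3 T). The coefficients live in `inst/extdata/trust_calibration.json`, not
in code, so a different published calibration can be swapped in without
touching the package. Haematocrit defaults are sex-specific — 0.42 for
males, 0.40 for females (`hct_default()`). `t2_to_yv()` inverts the
quadratic analytically and keeps the root inside the calibrated
oxygenation range (default 0.40–0.95); a $T_2$ that maps outside it
raises a range error naming the admissible $T_2$ interval rather than
extrapolating. Over the valid range the map is strictly monotone (checked
at construction), so the inverse is unique and composes with the forward
map to identity at machine precision. Arterial saturation defaults to
$Y_a = 98\%$.

## Flow integration and CBF

Phase-contrast MRI encodes through-plane velocity; integrating signed
velocity over a vessel cross-section gives volumetric flow:

$$Q = 60 \sum_{p \in \mathrm{ROI}} v_p \, A_p \quad \text{(ml/min)},$$

with $v_p$ in cm/s and pixel area $A_p$ in cm². Negative-phase pixels
contribute with their sign; an optional correction subtracts the median
velocity of the non-ROI background first (a constant phase-offset model —
the manual correction used on real data is operator-dependent and not
reproducible in code). Global CBF divides the summed inflow of the four
feeding arteries (left/right internal carotid, left/right vertebral) by
brain mass:

$$\mathrm{CBF} = \frac{\sum_k Q_k}{V_{\mathrm{brain}} \cdot \rho} \times 100
\quad \text{(ml/100g/min)},$$

with brain density $\rho = 1.06$ g/ml, the standard physiological
constant, recorded in the result object. A negative total flow is
physically suspect (a signed phase artefact) and is returned flagged with
a warning rather than silently accepted.

# Derived cohort variables

**Cognitive composites.** Raw test scores from the six-domain battery
(executive: colour trails A/B; attention: digit span forward/backward;
language: modified Boston Naming; visuomotor speed: SDMT; visuospatial:
Rey figure copy; memory: Rey figure and Hopkins verbal learning recall)
are Z-scored against the sample mean and SD. Two conventions are fixed
here because the field leaves them implicit: timed tests, where a larger
raw value means worse performance, are negated before standardisation so
higher Z is uniformly better; and the SD uses the $n-1$ denominator
throughout. Domain scores are means of their tests' Z-scores,
re-standardised; the global composite is the re-standardised mean of the
domain scores, hence sample mean 0 and SD 1 *by construction* — the suite
asserts this to $10^{-12}$, and standardising an already-standard column
is a no-op. All battery tests must be present; a zero-variance test is an
error naming the test. There is no available-test averaging for missing
items: rows must be complete, a deliberate divergence from ambiguous
practice, stated rather than hidden.

**WMH.** Volumes are right-skewed, so analyses use the natural log with a
0.01 cm³ floor offset (`log_wmh()`), making zero volumes finite and the
transform monotone. Subjects flagged with infarcts are excluded from all
WMH outcomes, since infarcts inflate lesion-volume estimates.

**Vascular risk.** The composite score counts hypertension, diabetes,
hyperlipidaemia, ever smoking and obesity — BMI *strictly* above
28 kg/m² — giving 0–5; scores 0–2 form the low-risk stratum, 3–5 the
high-risk stratum. Missing components are an error; no imputation.

**Quadrants.** Subjects are classified by median splits of OEF and CBF:
Q1 high/high, Q2 high OEF + low CBF (misery perfusion), Q3 low/low,
Q4 low OEF + high CBF. "High" means strictly above the sample median;
values equal to the median go low. The tie rule makes the split
deterministic, and labels are invariant under any strictly monotone
transform of either marker.

# Association models

`fit_linear()` is an identity-link Gaussian GLM — ordinary least squares
via QR — with the quadrant factor re-levelled to Q2 so every contrast is
against misery perfusion; the reference row is emitted explicitly as zero.
Confidence intervals are Wald normal-approximation intervals,
$\hat\beta \pm 1.96\,\mathrm{SE}$, with classical (model-based) standard
errors. `run_quadrant_battery()` runs the full table: log-WMH
(infarct-free subset; Model 1 age + sex, Model 2 + vascular risk score)
and the global composite plus six domains (Model 1 age + sex + education,
Model 2 + vascular risk score) — 8 outcomes × 3 contrasts × 2 models.
Sex enters as a 0/1 male indicator and education as a single ordinal
integer. `run_stratified()` refits the continuous OEF and CBF slopes
within vascular-risk or APOE4 strata, skipping (with a warning) strata too
small for the parameter count.

`mancova()` validates multivariate effects: covariates enter first, each
tested term is added sequentially, and its hypothesis cross-product
matrix is $H = Y'(P_j - P_{j-1})Y$ with error matrix
$E = Y'(I - P_{\mathrm{full}})Y$. Pillai's trace
$V = \mathrm{tr}\!\left[H (H + E)^{-1}\right]$ is converted to an F
statistic with the standard degrees-of-freedom approximation, and
follow-up univariate ANCOVA F tests are reported per outcome. The
matrices are computed in-package from QR projections and cross-checked in
the test suite against both an explicit eigenvalue-sum oracle and the
reference sequential MANOVA implementation.

# Response-surface analysis

The joint, potentially nonlinear dependence of an outcome $Z$ on OEF
($X$) and CBF ($Y$), both mean-centred, is modelled by the second-order
polynomial

$$Z = b_0 + b_1 X + b_2 Y + b_3 X^2 + b_4 XY + b_5 Y^2 + \text{covariates}.$$

Two lines in the $(X, Y)$ plane carry the physiological interpretation.
Along the **balance axis** ($Y = X$ in centred units: supply and
extraction move together) the surface has slope $b_1 + b_2$ and curvature
$b_3 + b_4 + b_5$; along the **bias (mismatch) axis** ($Y = -X$,
equivalently $\mathrm{CBF} = -\mathrm{OEF} + 2\mu$ in raw units) the slope
is $b_1 - b_2$ and the curvature $b_3 - b_4 + b_5$. `axis_tests()` forms
these linear combinations with delta-method standard errors,
$\mathrm{SE}^2 = c'\Sigma c$, from the stored coefficient covariance, and
Wald 95% intervals. Axis statistics are parametrised per unit of $X$
along the line (matching the $b_1 \pm b_2$ combinations), not per unit
arc length; the directional derivative along the balance line is
therefore $(b_1 + b_2)/\sqrt{2}$, a factor the tests verify numerically.

**Covariates: adjust versus residualize.** Field practice is ambiguous
between including covariates inside the polynomial regression and
pre-residualizing the outcome on them; the two give different
coefficients whenever covariates correlate with OEF/CBF. Both are
implemented — `mode = "adjust"` (primary) and `mode = "residualize"`
(sensitivity) — and every fit records which mode produced it.

**Centring.** `fit_rsa()` centres at sample means by default, stores the
constants with the fit, and also accepts known centring constants or
pre-centred data. The distinction matters for calibration exercises: when
data are generated from a surface defined at known centres, re-centring
at sample means shifts the intercept by
$b_3 \mathrm{Var}(\bar X) + b_5 \mathrm{Var}(\bar Y)$ and adds
$O(1/\sqrt{n})$ re-centring noise to the linear terms, so
parameter-recovery and coverage simulations fit at the generating
centres, where the estimators are exactly unbiased and the delta-method
intervals are calibrated. On real data, where no generating centre
exists, sample-mean centring is the correct default.

`predict_surface()` evaluates the fitted polynomial (the predicted
outcome *residual*, excluding covariates) on a 50×50 grid over the
observed centred ranges, clipped to ±2.5 SD, plus the two axis polylines,
as plain tables for any plotting layer; no 3-D rendering is attempted.

# The synthetic-data generator

`simulation_config()` + `generate_bundle()` produce all inputs the
pipeline consumes. Cohort-level structure:

* **OEF/CBF** are bivariate normal with means 39.7% / 58.2 ml/100g/min
  and SDs 4.45 / 8.95. Only marginal moments are established for such
  cohorts, so the correlation is an explicit knob, default 0; quadrant
  cell counts are *not* a calibration target.
* **WMH volumes** are log-normal (log-mean 0.486, log-SD 1.21, chosen to
  match a raw mean ± SD of 3.38 ± 6.16 cm³), floored at 0.01 cm³, so the
  downstream log transform is exactly normal. Optional log-scale quadrant
  shifts (applied at the sample-median split, so generation and analysis
  classify identically) support parameter-recovery experiments.
* **Demographics and risk factors**: age normal (67.8 ± 8.76 y), 31.08%
  male, education ordinal 0–4 at frequencies 16.2/34.8/22.0/14.9/12.2%,
  Bernoulli risk factors at prevalences 45.3/20.3/34.8/20.6%, 47.3%
  genotyped for APOE with 17.1% carriers, 14.2% infarct flags. The
  obesity flag is drawn first and BMI then sampled from the matching side
  of 28 kg/m²; at the default prevalence (the normal tail probability)
  the mixture reproduces exactly the configured N(24.2, 3.21²).
* **Cognition**: each domain latent is covariate effects (defaults:
  −0.02/year of age, 0 for sex, +0.15 per education level — values of the
  magnitude routinely seen for ageing cohorts) plus the prescribed
  second-order surface in centred OEF/CBF plus N(0, 1) noise. The default
  surface is the global-cognition coefficient set
  $(b_1, \ldots, b_5) = (-0.49, -0.03, 0.01, 0, 0)$; note these printed
  coefficients imply a stronger marginal OEF–cognition coupling than
  quadrant contrasts alone would suggest, and the generator treats them
  as the prescribed truth rather than re-deriving them. Raw test scores
  are affine transforms of the domain latents (loading 0.5 plus
  test-specific noise), with timed tests sign-flipped.
* **Signal level**: each subject's TRUST series uses the T2 obtained by
  inverting the calibration at the subject's sex-specific haematocrit
  (amplitude 1000, Gaussian noise 1% of $S_0$), and each velocity scene
  distributes the subject's total inflow —
  $\mathrm{CBF} \times V_{\mathrm{brain}} \times 1.06 / 100$, with brain
  volume N(1200, 100²) ml, a typical older-adult value — over four disc
  ROIs (38/38/12/12%) with a blunted plug-flow profile whose *noiseless
  discrete integral equals the requested flow exactly*, plus 0.5 cm/s
  velocity noise, clamped at the 40 cm/s venc. The blunted profile keeps
  peak velocities inside the venc across the physiological flow range; a
  requested flow whose peak would alias is refused rather than clipped.

Seeding is hierarchical: one master seed spawns independent child streams
for the cohort, TRUST and velocity components, so enabling or disabling a
component never perturbs the draws of another, and identical
(config, seed) pairs give byte-identical bundles.

**What the generator does not emulate** — and hence what green tests do
not show about real data: no k-space physics or artefact structure beyond
mono-exponential decay and additive Gaussian noise; no vessel geometry,
pulsatility or partial-volume effects; no lesion geometry or FLAIR
images; no item-level cognitive response processes; and exact
distributional assumptions (normality, log-normality, Bernoulli
independence) that real cohorts only approximate. Passing tests
demonstrate that the estimators recover the truth of *this* generative
mechanism at the configured signal-to-noise, not that the pipeline is
robust to acquisition pathologies.

# Problem sizes and numerical choices

The Monte-Carlo test suite uses the cohort scale throughout: T2
round-trips at 1000 replicates; RSA parameter recovery over 500 cohorts
of n = 296; balance-slope CI coverage over 1000 cohorts (95% ± 2% band);
quadrant-contrast type-I error over 2000 null cohorts (5% ± 1.5% band);
MANCOVA permutation uniformity over 1000 permutations, checked by a
Kolmogorov–Smirnov test. Key tolerances: nonlinear T2 refinement to
relative 1e-10; calibration inverse-consistency to 1e-9; OLS and Pillai
agreement with explicit linear-algebra oracles to 1e-10; grid predictions
against direct polynomial evaluation to 1e-12. Degenerate-input policy is
uniform: errors are classed conditions (`hemosurf_config_error`,
`hemosurf_input_error`, `hemosurf_fit_error`, `hemosurf_range_error`,
`hemosurf_domain_error`) raised early with the offending quantity named.

# Orchestration

`run_pipeline()` executes simulate → quantify → prepare → analyze → rsa
from a single `run_config()`, handing results between stages and writing
every product as CSV plus a `manifest.json` recording the seed, package
version, the design-decision set in effect, per-stage status and outputs.
Runs are idempotent for a fixed seed. Disabling the quantify stage makes
downstream stages consume the generator's true OEF/CBF columns — with
noiseless signals the two routes agree, which the suite checks. A thin
command-line wrapper ships in `inst/scripts/hemosurf-pipeline.R`
(exit codes: 0 success, 2 configuration error, 3 data error).

# Known limitations

* The haematocrit calibration coefficients come from the cited
  literature's published law, not from any cohort-specific calibration;
  they are configuration, and results depend on them through $Y_v$.
* Classical (non-robust) standard errors and Wald intervals throughout;
  no bootstrap, no multiple-testing correction, matching the analysis
  this package operationalises.
* The RSA "residualize" mode is a sensitivity analysis, not a second
  primary estimate; adjusted and residualized coefficients differ by
  construction when covariates correlate with the exposures.
* WMH response surfaces use the log-volume scale for consistency with the
  rest of the pipeline; raw-volume surfaces are not implemented.
* No image registration, vessel auto-segmentation, cardiac gating, or
  lesion segmentation: velocity maps arrive with ROI masks, and WMH and
  brain volumes are inputs.
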