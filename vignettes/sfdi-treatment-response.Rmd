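---
title: "Simulating and analyzing SFDI monitoring of tumor treatment response"
author: "sfdiresponse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing SFDI monitoring of tumor treatment response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`sfdiresponse` is a simulation-plus-analysis pipeline for spatial frequency
domain imaging (SFDI) of murine tumors under chemotherapy. It covers the
full measurement chain — structured-illumination image synthesis,
three-phase demodulation, phantom calibration, in-frame drift correction,
surface height/angle correction, two-frequency lookup-table inversion to
optical properties, spectral fitting to hemodynamic and scattering
biomarkers, ROI aggregation and baseline normalization — and the
longitudinal statistics on top of it: generalized estimating equations
(GEE) with per-day group contrasts, and leave-one-out cross-validated
linear discriminant classification of treatment arms.

The study design it emulates is a paired responsive/resistant breast-tumor
model: an untreated Control arm (n = 3), a metronomic-cyclophosphamide arm
(CPA, n = 9) that regresses through an immune-mediated mechanism, and a
CPA + IFNAR-1-antibody arm (CPA+Ab, n = 14) in which that mechanism is
blocked, yielding treatment resistance. Measurements run daily on Days 0–6
and every third day through Day 30; all Controls leave the study by
Day 12, and about half of each treated arm is euthanized on Day 12.

## Forward model

The optics core uses the steady-state diffusion approximation for a
homogeneous semi-infinite medium under sinusoidal illumination at spatial
frequency $f_x$:

$$R_d(f_x) = \frac{3 A a'}{(\mu_{eff}'/\mu_{tr} + 1)(\mu_{eff}'/\mu_{tr} + 3A)},
\qquad
\mu_{eff}'(f_x) = \sqrt{3\mu_a\mu_{tr} + (2\pi f_x)^2},$$

with $\mu_{tr} = \mu_a + \mu_s'$, reduced albedo $a' = \mu_s'/\mu_{tr}$,
and the internal-reflection parameter $A$ computed from the effective
reflection coefficient of the refractive mismatch
($R_{eff} \approx 0.0636\,n + 0.668 + 0.710/n - 1.440/n^2$; $n$ defaults
to 1.4, a typical tissue/air value, and is configurable). The model
satisfies the physical limits the tests assert: $R_d \to 1$ as
$\mu_a \to 0$ at $f_x = 0$, and $R_d$ decreases strictly in both $f_x$
and $\mu_a$. Against an independent Monte-Carlo photon random walk
(isotropic-similarity transport, Fresnel boundary) it agrees within ~1%
at the calibration-phantom properties, inside the diffusion regime's
expected accuracy.

A deliberate simplification: commercial murine SFDI processing uses a
two-layer (skin + tumor) lookup table whose fixed skin parameters are not
public. This package uses the homogeneous semi-infinite model for both the
generator and the inversion. That biases *absolute* recovered properties
relative to a layered instrument, but every analysis endpoint here is a
percent change from the subject's Day-0 baseline, which cancels
systematic multiplicative bias; it also makes the whole chain exactly
testable, because synthesis and analysis share one forward model.

Scattering follows the power law $\mu_s'(\lambda) = a(\lambda/800)^{-b}$
with amplitude $a$ (mm⁻¹ at 800 nm) and power $b$; absorption follows
Beer's law over oxy- and deoxy-hemoglobin,
$\mu_a(\lambda) = \varepsilon_{HbO_2}(\lambda)\,ctHbO_2 +
\varepsilon_{HHb}(\lambda)\,ctHHb$, with composites
$ctTHb = ctHbO_2 + ctHHb$ and $StO_2 = ctHbO_2/ctTHb$. The packaged
extinction table (`inst/extdata/hemoglobin_extinction.csv`) is
interpolated from the standard compiled hemoglobin spectrum at the four
instrument wavelengths (659/691/731/851 nm), converted to mm⁻¹·µM⁻¹; the
conversion is documented in the file header and covered by a unit test.
Water and lipid are not fit. The power-law fit is closed-form linear
regression in log–log coordinates (at four wavelengths the difference
from a nonlinear fit is negligible and the closed form is deterministic);
the chromophore fit is non-negativity-constrained least squares, because
concentrations are physical — a negative unconstrained solution clamps to
the boundary.

## The synthetic study

The generator is a first-class, tested component, not a fixture. Its
defaults are the study conditions.

**Trajectories.** Group-mean biomarker time courses are piecewise-linear
curves through the study's characteristic anchors: CPA scattering
amplitude +9% at Day 5 rising to ~+45% by Day 30; CPA+Ab and Control
near −10% at Day 5; ctHHb spiking to ~+60% in Controls over Days 3–6 then
declining, dipping slightly early in both treated arms before climbing to
plateaus of ~+50% (CPA) versus ~+25% (CPA+Ab); volume growing
exponentially in Controls, rising to Day 3 then regressing under CPA, and
rising linearly to ~Day 9 then plateauing under CPA+Ab. Values between
anchors are interpolation, not claims. Day-4 volume means of the two
treated arms are nearly equal by construction of the two curves' shapes
(one arm has peaked, the other is still climbing) — this is what makes
volume an uninformative Day-4 classifier while scattering already
separates the arms.

**Subject structure.** Each subject draws a lognormal baseline per
biomarker (volume 250 mm³ at enrollment, tumor $a$ 1.2 mm⁻¹, $b$ 1.3,
ctHbO₂ 60 µM, ctHHb 40 µM; CVs 5–10%) and one trajectory multiplier per
biomarker (mean 1, sd 0.15, truncated to [0.4, 1.6]); day-level additive
noise on the percent-change scale (sd 2 for $a$ and $b$, 4–5 for
hemoglobin, 8 for volume) models biological and measurement-day
fluctuation. No within-group variability is reported numerically by the
emulated study, so these spreads are the package's own calibration,
chosen once so that Day-5 group separations and classification accuracies
bracket the reported figures; they are recorded in the committed default
configuration (`inst/extdata/default_cohort_config.yaml`).

**Scenes and raw images.** The tumor is a hemispherical cap whose
footprint radius follows $V = \tfrac{2}{3}\pi r^3$; inside the footprint
optical properties come from the subject's biomarkers via the power law
and Beer's law, outside from configured normal-tissue values, and an
in-frame phantom patch (same material as the calibration phantom) sits in
a corner. Height and surface-normal angle maps are the exact cap
geometry, so the fraction of footprint pixels at or below the 40° angle
threshold is analytically $\sin^2 40^\circ \approx 0.413$ — a closed-form
check the tests use. Raw stacks contain one frame per (wavelength ×
frequency × phase): planar frames carry $gain \cdot hf \cdot \cos\theta
\cdot R_d(0)$ and AC frames add the sinusoid
$mtf \cdot R_d(f_x)/2\,\cos(2\pi f_x x + \phi)$, where $hf = 1 + k_h h$
is a linear height intensity factor ($k_h = -0.02$/mm, stored in the
instrument config so preprocessing can invert it exactly — a synthetic
stand-in for profilometry-calibrated height correction, which needs the
physical instrument), plus Gaussian noise with sigma 1% of the local DC
signal. Each acquisition carries a lognormal session gain drift
(sd 2%) relative to that day's calibration measurement. The default grid
is 64×64 px at 0.5 mm pitch, a desk-scale reduction of the instrument's
150×200 mm field chosen so a full 26-subject, 306-acquisition cohort
simulates and processes in well under a minute; grid size is
configurable. Not emulated: skin/fur layered optics, breathing motion,
camera PSF, specular reflection, intratumoral heterogeneity (the analysis
uses ROI means only). Passing tests therefore validate the processing
chain and statistics under this generative model, not instrument physics
beyond it.

## Processing-chain choices

- **Demodulation** uses the exact three-phase identities
  $M_{AC} = \tfrac{\sqrt2}{3}\sqrt{(I_1-I_2)^2+(I_2-I_3)^2+(I_3-I_1)^2}$,
  $M_{DC} = (I_1+I_2+I_3)/3$, exact on any 120°-spaced sinusoid.
- **Calibration** ratios the sample against a measured reference phantom
  with known properties and multiplies by the model reflectance. Because
  a calibration acquisition's noise becomes a *shared* error in every
  measurement calibrated against it, `process_cohort` first denoises the
  calibration maps: a homogeneous-phantom acquisition has rank-1
  structure (spatial illumination profile × per-channel scalar), so the
  profile is estimated from the pooled, lightly blurred planar channels
  and each channel is rebuilt from it (`smooth_calibration`). This
  assumes the spatial response is shared across channels — true of a
  projector gain profile; per-channel box-blurring is available as a
  fallback for instruments with frequency-dependent spatial response.
- **Drift correction** rescales each wavelength so the in-frame phantom
  mean matches its calibration-time value (the model reflectance of the
  patch material, i.e. the idealized first measurement of the day). One
  factor per wavelength is estimated from the planar channel and applied
  to both frequency channels: drift is physically a scalar
  illumination/camera gain, and the AC in-frame mean (small patch, small
  modulation amplitude) is too noisy to estimate it independently without
  injecting error. Per-channel factors remain available
  (`per_channel = TRUE`).
- **Surface correction** divides by the Lambertian $\cos\theta$ and the
  height gain factor, then invalidates pixels steeper than 40°; the mask
  is applied before ROI averaging, and corrections never resurrect
  already-invalid pixels.
- **Inversion** maps each pixel's $(R_d(0), R_d(0.1))$ pair to
  $(\mu_a, \mu_s')$ by damped Newton iteration on the log-property plane
  (numeric Jacobian, step cap of one log-unit, residual tolerance 1e-7),
  seeded at the lookup-table center with a coarse-grid nearest-node
  re-seed for stragglers. The LUT grid is log-spaced in $\mu_a$ over
  [0.001, 0.5] mm⁻¹ and linear in $\mu_s'$ over [0.2, 3.5] mm⁻¹ — ranges
  chosen to bracket the phantom values and the full span of simulated
  tumor trajectories (late-study responsive tumors reach
  $\mu_s'(659) \approx 3$ mm⁻¹). Reflectance pairs outside the model's
  attainable set, or solutions outside the grid ranges, are flagged
  invalid rather than extrapolated; at the attainable-set boundary ties
  resolve to invalid. Because Newton refinement solves the forward model
  directly, inversion error is tolerance-limited rather than
  grid-limited; the tests assert it does not degrade with grid density
  rather than that it improves.
- **ROI aggregation** uses the ground-truth tumor mask eroded by one
  pixel as a reproducible stand-in for manual ROI selection, intersected
  with the validity mask, excluding artifact pixels with
  $\mu_a(659) < 0.002$ mm⁻¹ (the "extremely low absorption" floor is not
  quantified by the emulated protocol; it is a config knob). Tumor volume
  uses the caliper formula $V = (3.14/6)(LW)^{3/2}$ with the literal
  constant 3.14 for fidelity to the animal protocol. Percent change is
  $100(x_d - x_0)/x_0$; subjects without a usable Day-0 baseline are
  excluded with a logged reason.

## Statistics

**GEE.** Percent-change outcomes are modeled population-averaged with
categorical day, treatment group, and their interaction (the per-day
post-hoc contrasts require per-day terms), normal family with identity
link, subjects as clusters, AR(1) working correlation (moment estimate on
within-cluster residual lag-1 products by observation order), and
cluster-robust sandwich covariance. The estimator is implemented in
`R/gee.R` — it is a short, transparent iteration whose every moment
estimate is visible to the tests — and verified against ordinary least
squares in the independence limit (exact identity) and against cell
means for saturated models on balanced data.
Two scopes mirror the study: short-term (all three arms through Day 12,
while every arm has subjects) and long-term (CPA vs CPA+Ab through
Day 30). Contrast significance is flagged at 0.05 and at the
multiplicity-adjusted thresholds 0.007 (short) and 0.003 (long); the
adjusted thresholds are taken as given constants of the emulated
analysis, since the divisor rule that produced them is not stated.

**LDA.** The classifier is the pooled-covariance Gaussian discriminant
with equal priors (group sizes are by design, not prevalence), evaluated
by subject-level leave-one-out cross-validation; accuracy is
correct/total. Features are percent changes, consistent with the
baseline-normalization convention of the whole analysis. Singular pooled
covariances are ridge-regularized with an escalating epsilon recorded on
the model object; ties in discriminant scores break toward the larger
prior, then the lexicographically smaller label. It is implemented
in-package for exact control of these conventions and cross-checked in
tests against both `MASS::lda` and a brute-force discriminant computed
from explicit Gaussian densities. Accuracy grids evaluate each feature
set (volume; $a$; ctHHb; $b$; StO₂; ctHHb + $a$) at each day — Days 1–6
for the three-group short-term grid, all post-baseline days for the
two-group long-term grid — with cells requiring at least two subjects
per group.

## Numerical and degenerate-input conventions

Validity masks only shrink along the chain. The diffusion model warns
(without failing) when $\mu_s'/\mu_a < 10$, outside its comfort zone.
`StO2` is undefined (flagged, NA) at zero total hemoglobin. Zero-noise
configurations are exactly reproducible: the generator realizes all
trajectory-level randomness before any image synthesis, so the
ground-truth table is identical whether or not images are rendered
(`render = FALSE` supports statistics-level simulation studies at
trajectory speed). All randomness flows from the config seed; identical
configs give bit-identical cohorts.

## Problem sizes

Default analyses use the full 26-subject design at 64×64 px: one cohort
generates and processes in roughly 20 s. The packaged acceptance script
repeats the complete pipeline over 10 seeded cohorts (~3 minutes); the
test suite's heavier end-to-end checks share those runs through a
memoized fixture. The Monte-Carlo forward-model oracle value frozen in
the tests was computed at 5×10⁵ photons; a smaller live run guards the
oracle itself.

## Known limitations

Absolute optical properties carry the homogeneous-model bias discussed
above; only relative (percent-change) endpoints should be compared across
instruments. The generator's noise model is calibrated, not measured —
conclusions about real-data classification accuracy do not follow from
the synthetic accuracies, only the *ordering* of feature sets under the
configured effect sizes. The AC reflectance surface loses monotonicity in
$\mu_a$ at very low absorption and scattering (the frequency term
dominates the transport scale there), which is why inversion validity is
defined by residual and grid-range checks rather than monotonicity.
Contralateral/healthy-tissue ROIs, depth sectioning, and spatial
heterogeneity statistics are out of scope.
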