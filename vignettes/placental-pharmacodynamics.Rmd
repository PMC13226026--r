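---
title: "Simulating and analysing longitudinal multimodal placental imaging studies"
author: "placentapd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing longitudinal multimodal placental imaging studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placentapd)
```

## The scientific problem

Drug development for preeclampsia lacks sensitive, non-invasive readouts of
the placenta's response to therapy. The classical bedside metric — the
uterine artery resistance index (UtA-RI) — reflects the anatomical extent of
spiral-artery remodeling, so it can stay refractory even while tissue-level
oxygenation and perfusion are recovering. A longitudinal multimodal imaging
design addresses this by following the *same* placenta in the *same* dam
across gestation with four complementary modalities:

* **photoacoustic oximetry (sO~2~)** — hemoglobin oxygen saturation from
  dual-wavelength (750/850 nm) excitation, a proxy of tissue oxygenation;
* **contrast-enhanced ultrasound (WiAUC)** — the wash-in area under the
  bolus time–intensity curve, a velocity-independent surrogate of relative
  microvascular blood volume;
* **microvascular flow imaging (VI)** — the percentage of above-threshold
  flow pixels in the placental ROI, a microvascular-density surrogate;
* **pulse-wave Doppler (UtA-RI)** — `(PSV − EDV)/PSV` averaged over 3–5
  cardiac cycles, the macrovascular resistance readout.

Two exploratory pharmacodynamic statistics integrate these longitudinal
profiles. The **recovery slope** is the per-subject OLS slope of a marker
against gestational day (GD), sign-flipped for markers where a decrease
means improvement, so positive always means movement toward the healthy
phenotype. The **Functional Recovery Index**

$$\mathrm{FRI} = 100 \times
  \frac{X_i - \bar X_{\mathrm{disease}}}
       {\bar X_{\mathrm{control}} - \bar X_{\mathrm{disease}}}$$

normalizes a treated subject's endpoint value onto a common percent scale:
100 is full normalization to the healthy control level, 0 is no improvement
over the untreated disease phenotype, and negative values indicate further
deterioration. FRIs are affine-invariant and are reported unclipped in both
directions.

Because no subject-level data are deposited for the motivating three-arm
rat study (L-NAME-induced disease, statin rescue, n = 8 dams/arm), the
package is built around a *synthetic cohort generator* calibrated to that
study's published group-level endpoints, slopes and FRIs, plus forward
models of all four measurement chains. The full pipeline therefore supports
closed-loop validation: the calibrated truths go in, raw signals are
simulated, quantified, and summarized, and the recovered slopes and FRIs
can be compared against the calibration.

## The generative model

### Trajectories

For marker $m$, arm $g$, the true group mean follows an anchor-and-slope
line

$$\mu_{mg}(t) = a_{mg} - b_{mg}\,(t_{\mathrm{anchor}} - t),$$

with the anchor day at GD18. Each dam adds a time-constant random intercept
with SD $\tau_m$, and each imaging session adds a biological fluctuation
with SD $\sigma_m$ before the instrument chain sees it. Trajectories are
linear per arm over the observation window: the underlying biology is
piecewise (the intervention starts at GD10), but only endpoint anchors and
fitted slopes are published, so the piecewise shape is absorbed into the
calibrated slopes. There is no random slope by default (the printed
slope dispersions are consistent with session noise alone; see below).

### Calibration: published values in, free defaults flagged

Printed quantities enter the default calibration unchanged: disease/treated
endpoint means and slopes for systolic blood pressure (162.9/143.9 mmHg;
3.91/2.15 mmHg/day) and 24-h urinary protein (662.6/506.3 mg/L;
43.84/29.55 mg/L/day); disease/treated slopes for the four imaging markers;
and all six endpoint FRIs (51.1, 32.0, 92.7, 88.1, 68.3, 43.9 %). Healthy
control values were never printed, so the remaining anchors are
reconstructed by inverting the FRI relation:

* systemic control anchors: $\bar X_C = \bar X_{PE} + (\bar X_T - \bar
  X_{PE})/\mathrm{FRI}$, giving 125.7 mmHg and 174.2 mg/L; their slopes are
  set so all three arms share the GD7 baseline already implied by the
  printed disease/treated lines (120 mmHg, 180 mg/L) — a consistency the
  calibration inherits rather than imposes;
* imaging control/disease anchors are physiological defaults (sO~2~
  70/48 %, WiAUC 30000/18000 a.u., VI 40/25 %, RI 0.55/0.75) and the
  treated anchors follow by the forward FRI relation, e.g. sO~2~
  $48 + 0.927 \times 22 = 68.394$ %.

Dispersions: printed "±" values are SEMs with n = 8, so SDs default to
SEM × √8. The imaging markers print no marker-level dispersion at all; their
between-subject SDs are derived from the *FRI* SEMs, which measure exactly
the treated-arm marker dispersion divided by the reference gap:
$\tau_m = \mathrm{SEM}_{FRI}\sqrt{8}/100 \times |\bar X_C - \bar X_{PE}|$
(4.11 sO~2~ points, 2138 a.u., 8.06 VI points, 0.0249 RI). One pleasant
consistency check: with session noise ≈ 1 sO~2~ point the implied
per-subject slope SD over GD14/16/18 is ≈ 0.39 %/day, close to the printed
slope SEM × √8 ≈ 0.34 %/day — which is why the generator needs no random
slope component.

### Couplings

A latent per-dam "functional rescue" factor $z \sim N(0,1)$ loads on the
subject intercepts of the functional markers (sO~2~ 0.85, WiAUC 0.88,
VI 0.3) but **not** on arterial resistance, and fetal weight correlates with
$z$ at 0.85 within each arm. These loadings reproduce the published
dissociation qualitatively — treated-arm fetal weight correlates with the
functional FRIs (r ≈ 0.7) but not with the resistance FRI — and the exact
correlation values are deliberately not acceptance-bearing. Endpoint
histology is linear in the endpoint truths: the hypoxia marker decreases in
sO~2~ (calibrated to ≈ 5 % positive area in controls, ≈ 25 % in disease)
and the endothelial marker increases in microvascular density, with noise
SDs chosen to give pooled correlations near the published −0.75 and 0.63.

### Clipping, not resampling

Structural invariants (fractions in [0, 1], EDV ≤ PSV, non-negative
weights, percentages in [0, 100]) are enforced by clipping with a warning,
never silent resampling, so violations remain auditable. One deliberate
exception: the urinary-protein simulation support extends below zero.
With the endpoint dispersion of 131.3 × √8 ≈ 371 mg/L carried back to GD7
(mean ≈ 180 mg/L), an additive Gaussian intercept model necessarily
produces negative excursions in ≈ 30 % of early-gestation disease-arm
values; truncating them at zero would inflate the early means and bias the
calibrated disease slope by ≈ −14 %. Since the slope, not the marginal
positivity, is the calibrated quantity, the generator keeps the linear-
Gaussian model intact and documents the unphysical tail here.

## Measurement models

**Photoacoustics.** ROI-mean amplitudes follow
$p_\lambda = \Phi_\lambda(\varepsilon_{HbO_2,\lambda} C_{HbO_2} +
\varepsilon_{Hb,\lambda} C_{Hb}) + \text{noise}$ with standard hemoglobin
extinction values at 750/850 nm (Hb 1405.24/691.32, HbO~2~ 518.0/1058.0
cm⁻¹M⁻¹). Unmixing solves the 2×2 system assuming equal fluence at both
wavelengths and returns $C_{HbO_2}/(C_{HbO_2}+C_{Hb})$; it is the exact
inverse of the forward model in the noiseless equal-fluence case, and
invariant to common fluence magnitude. Wavelength-dependent fluence can be
configured to study the resulting systematic bias; the fixed imaging depth
of the motivating protocol is absorbed into a constant. ROI-scalar
simulation is the default because the published quantities are ROI means.

**Contrast bolus curves.** The lognormal bolus model
$I(t) = O + A\,\mathrm{lognormal}(t - t_0;\mu,\sigma)$ is the de-facto
standard form in bolus-quantification software; the commercial tool used
in the motivating study does not publish its internal model, so the
lognormal form with the wash-in bound at the fitted time-of-peak is a
design choice (the raw-curve trapezoidal integral is available as an
option). The amplitude is parameterized so the *true wash-in AUC equals
the blood-volume ground truth*, making the chain calibration-transparent.
Fitting is bounded Levenberg–Marquardt with moment-based initialization on
a smoothed curve (arrival = last sub-5 %-of-peak sample walking back from
the peak; log-moments for $\mu, \sigma$) and deterministic perturbed
restarts; flat curves (enhancement < 5× the sample-difference noise
estimate) are flagged and their metrics set missing. Default kinetics
($t_0$ = 5 s, $\mu$ = 3.38, $\sigma$ = 0.4, 60 s at 2 Hz) put the peak
near 30 s, matching the acquisition sketched in the motivating protocol.
WiAUC is evaluated analytically as $A\,\Phi_{\mathrm{lognormal}}(e^{\mu -
\sigma^2}) = A\,\Phi(-\sigma)$.

**Doppler.** Per-cycle PSV/EDV readings are truth plus independent
Gaussian noise (5 cycles, 2 mm/s by default); the RI is the per-cycle
ratio averaged over cycles. EDV truth derives from the RI truth at a
calibrated PSV of 60 mm/s.

**Flow maps.** A 256×256 binary vessel field with occupancy equal to the
density truth (vessel count = rounded expected count), contrast 10 a.u.
over N(0, 1) background, constant threshold 5 a.u. across all subjects and
sessions. The expected VI equals the true density; the binomial SE at
256² pixels is ≈ 0.2 %.

## Inference

The classical procedures are implemented from sums-of-squares and
distribution formulas with explicit choices where the motivating analysis
is silent:

* **Mixed RM-ANOVA** (between = arm, within = session, subject = dam):
  classical balanced decomposition; Greenhouse–Geisser correction is
  implemented and **on by default** for within-subject effects. Post hoc
  arm contrasts at each session are pooled-variance t-tests with Bonferroni
  multiplication by the number of pairwise comparisons at that session
  (three), capped at 1.
* **Slope comparison**: the pooled model `value ~ gd * group` with an
  F-test on the interaction (homogeneity of slopes). On random-intercept
  longitudinal data this pooled test is *conservative* — the residual
  absorbs between-subject intercept variance that does not propagate into
  slope estimates — so a per-subject-slope two-sample t-test is always
  reported alongside as the sensitivity analysis. The published
  significance profile of the systemic slopes is reproducible only at the
  subject-slope level, which is consistent with the printed slope SEMs
  being per-subject dispersions. Note the two tests are *not* related by
  F = t²: they use different error strata and degrees of freedom.
* **FRI comparison across modalities**: one-way ANOVA with Tukey HSD via
  the studentized-range distribution (Tukey–Kramer SEs).
* **Correlation/regression**: product-moment r with the t-based two-tailed
  test; OLS by the normal equations.
* Two-tailed tests throughout; normality/homoscedasticity screening is a
  deliberate exclusion (assumption checks, not results-bearing).

## Numerical behaviour and degenerate inputs

With every SD set to zero ([calibration_zero_noise()] plus
`measurement_protocol(noiseless = TRUE)`) the pipeline collapses onto its
calibration — the strongest whole-system test. Two operators bound how
exactly: the kinetic fit is an iterative nonlinear solve (observed ≤ 10⁻⁶
relative on noiseless curves) and the VI is a pixel count quantized at
1/65536 per map. Everything else returns the calibrated slopes and FRIs to
floating-point round-off.

Other explicit degenerate-input rules: identical ANOVA cells give F = 0,
p = 1 rather than 0/0; an FRI whose reference means differ by less than a
relative guard (10⁻⁹, configurable) is a hard "degenerate reference" error
so the marker is excluded visibly; slopes need ≥ 2 distinct days; RI needs
positive systolic velocities; an empty ROI is an error; a flat bolus curve
is a flagged fit, not a zero.

## What the simulation does and does not establish

Passing the packaged checks shows that the *measurement-and-metrics chain
is consistent*: unbiased enough that 200 replicate cohorts recover the
calibrated FRIs within ±2 points and slopes within a few percent, with
correctly calibrated type-I error for the slope-comparison test under its
own assumptions. It does **not** validate the biology: the generator's
trajectories are linear by construction, session noise is Gaussian and
independent, no fetal resorption, litter-size effects, within-dam placental
heterogeneity, pharmacokinetics, or acoustic/optical physics (speckle,
depth-dependent fluence, bubble destruction) are modeled.

Two internal tensions of the published numbers surface honestly in the
simulation and are left as-is rather than tuned away:

* the VI contrast at GD18 (10.2 points) against the subject SD implied by
  the printed VI FRI SEM (8.06 points) yields only ≈ 45 % Bonferroni power
  at n = 8 — the printed p < 0.001 for that contrast is not reproducible
  under the printed dispersion, so the temporal-ordering check treats VI by
  its onset *ordering* (detection frequency rising toward GD18) rather
  than a majority threshold;
* the printed disease/treated RI slopes (+0.01 vs −0.005/day) genuinely
  differ, so a calibrated simulation detects the slope difference that the
  motivating analysis reported as non-significant, and the RI response
  label comes out "trajectory inversion" rather than "no slope
  alteration".

The per-cohort mean FRI is a ratio estimator; its denominator
$\bar X_C - \bar X_{PE}$ is itself noisy, which inflates the
replicate-to-replicate spread (most visibly for VI, whose reference gap is
only ≈ 1.9 subject SDs) and adds a small positive bias (≲ 1.5 points for
VI, ≲ 0.5 elsewhere) that stays inside the ±2-point recovery band.

## Problem sizes and reproducibility

The packaged study conditions are the published design: 3 arms × 8 dams,
systemic sessions at GD 7/10/13/18, imaging at GD 14/16/18, one monitored
placenta per dam. Calibration recovery uses 200 replicate cohorts
(`run_study(seed, replicates = 200)`, ≈ 4 minutes on one core, dominated
by 14,400 kinetic fits and as many 256² flow maps); the type-I calibration
of the slope test uses 1000 null simulations; distribution oracles use 10⁵
Monte-Carlo draws. Replicate *i* uses seed `seed + i − 1` for biology and
an offset stream for instrument noise, so any single replicate can be
regenerated in isolation; identical configuration and seed give
byte-identical outputs.

```{r example, eval = FALSE}
library(placentapd)
study <- run_study(seed = 1, replicates = 200)
study$summary        # per-marker slopes, FRIs, response patterns
study$contrast_freq  # Bonferroni-significant contrast frequencies by session
```

## Known limitations

* Control-arm anchors are reconstructions; any systematic error in the
  published FRIs propagates into them.
* The equal-fluence unmixing assumption hides wavelength-dependent
  attenuation; the config knob exists precisely to study that bias.
* The pooled slope-comparison test is conservative under random
  intercepts; consumers who want the published significance profile should
  read the per-subject-slope sensitivity column.
* The bolus-fit arrival time is bounded away from the observed peak, so
  pathological curves whose true arrival is at the peak sample are flagged
  rather than fitted.
* FRI ratio noise: with reference gaps below ≈ 2 subject SDs the index
  becomes heavy-tailed; the package reports it unclipped and leaves
  robustification (e.g. trimmed reference means) to the analyst.
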