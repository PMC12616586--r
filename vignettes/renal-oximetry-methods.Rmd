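---
title: "Whole-organ renal oximetry: models, simulation design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-organ renal oximetry: models, simulation design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The measurement chain

`renoxi` implements the analysis chain of whole-organ renal MR oximetry
under a graded isocapnic hypoxia challenge. A single interleaved
acquisition at a vessel cross-section yields five background-suppressed
T2-prepared magnitude images at increasing effective echo times and five
phase-contrast velocity maps. From these, per acquisition:

1. the ROI-mean signal across the five effective TEs is fit to a
   mono-exponential, `S(TE) = S0 exp(-TE / T2)`, giving the blood-water T2;
2. T2 is converted to venous oxygen saturation (SvO2) through a
   hematocrit-dependent calibration model;
3. the ROI-mean through-plane velocity times the ROI area times 60 gives
   the blood flow rate (BFR, mL/min), averaged across the five maps.

With arterial saturation (SaO2) from pulse oximetry, hematocrit from a
hemoglobin finger-prick (`Hct(%) = Hb / 0.34`), and kidney mass from an
anatomical scan (volume x 1.06 g/mL), Fick's Principle gives the renal
metabolic rate of oxygen in (umol O2/min)/100 g:

$$ rMRO_2 = \frac{C_{RBC}\,Hct}{\text{mass}} \; BFR \; (SaO_2 - SvO_2) \times 100 , $$

with $C_{RBC} = 19.93$ umol O2 per mL of red cells. Measuring the
inferior vena cava (IVC) above and below the renal-vein confluence gives
the *bilateral* rate: the flow difference $Q_{Vs} - Q_{Vi}$ is the total
renal venous outflow and the venous term is the flow-weighted mixture
$(Q_{Vs} SvO_2^s - Q_{Vi} SvO_2^i) / (Q_{Vs} - Q_{Vi})$. The expanded
form $Q_{Vs}(SaO_2 - SvO_2^s) - Q_{Vi}(SaO_2 - SvO_2^i)$ is algebraically
identical; both code paths exist (`bilateral_rmro2(form =)`) and are
asserted equal in the tests.

## The calibration model and its default coefficients

Blood-water transverse relaxation follows a Luz-Meiboom-type exchange
model: the rate $R_2 = 1/T_2$ is quadratic in the deoxygenated fraction
$(1 - Y)$ with hematocrit-dependent coefficients,

$$ R_2(Y, Hct) = A(Hct) + B(Hct)(1 - Y) + C(Hct)(1 - Y)^2 . $$

Published coefficient sets are specific to field strength and the
refocusing interval of the T2 preparation, and any set can be supplied as
a YAML config (`calibration_model()`, `read_calibration_yaml()`). The
bundled default, `"renal-3T-v1"`, is anchored so that at Hct 0.42 it
passes exactly through three representative renal-venous operating points
at 3 T -- (159 ms, 92%), (125 ms, 83%), (100 ms, 76%) -- spanning
normoxia to moderate hypoxemia. Away from Hct 0.42, the
deoxygenation-dependent terms $B$ and $C$ scale linearly with hematocrit
(plasma shows no deoxyhemoglobin effect) and $A$ interpolates linearly
from a plasma-like 1.4/s at Hct 0. Construction validates that $R_2$ is
positive and strictly decreasing in $Y$ over the whole validity domain
(Hct 0.15-0.60, SvO2 0.20-1.00).

The inverse solves the quadratic in $(1-Y)$ in closed form and picks the
root on the monotone branch. A measured T2 outside the admissible range
fails loudly with that range in the message -- silent clamping would bias
AVDO2 -- except that the pipeline allows a 5% relative band just past the
fully-oxygenated maximum, mapping such fits to the boundary saturation
with a note: at high SvO2 the forward map is flat, and measurement noise
routinely pushes a fitted T2 a fraction of a percent past the maximum.
Values beyond the band still fail.

## What the synthetic data emulates

The generator reproduces the statistical structure the analysis assumes,
not scanner physics:

* **Cohort** (`generate_cohort()`): attributes drawn from truncated
  normals matching a healthy adult cohort (e.g. left kidney mass
  172 +/- 29 g, range 124-226; hematocrit 42% +/- 4%, range 34-46%,
  derived from hemoglobin by the 0.34 rule). Truncation at the observed
  ranges shifts means slightly off the nominal center; tests compare
  against the analytic truncated-normal mean.
* **Condition truth** (`generate_condition_truth()`): per-condition
  marginal means/SDs for SaO2, site-wise SvO2 and BFR over the four
  stages (baseline, mild hypoxia at end-tidal O2 62 mmHg, moderate at
  52 mmHg, recovery). A subject-level offset -- by default 50% of the
  between-subject SD, shared across conditions with the residual scaled
  to preserve the marginal SD -- makes repeated measures within a subject
  correlated, so the repeated-measures ANOVA has non-trivial structure.
  Constraints are enforced by redrawing: SvO2 strictly between a 30%
  floor and SaO2, positive flows, suprarenal IVC flow above infrarenal.
* **Images** (`render_t2prep_series()`, `render_velocity_series()`):
  vessel pixels decay mono-exponentially from `S0` with the calibration's
  forward T2; the background carries 2% residual signal (imperfect
  suppression); Rician noise (magnitude statistics) is applied per pixel.
  Velocity maps follow a parabolic (Poiseuille) profile scaled so that
  the *discrete* ROI mean times area times 60 equals the true flow
  exactly, with additive Gaussian velocity noise (phase noise inside the
  VENC limit is additive to first order); rendering refuses flows whose
  peak velocity would alias (`|v| > VENC`).

Defaults: 64 x 64 matrix at 1.2 mm (vessel cross-sections ~1.1 cm^2 for
the renal vein, ~2.9 / ~2.2 cm^2 for the supra/infrarenal IVC),
VENC 60 cm/s, effective TEs {0, 40, 80, 160, 240} ms chosen to span the
observed venous T2 range (~70-170 ms), vessel SNR 50 at TE 0,
velocity-map noise 0.5 cm/s, five acquisitions per condition averaged on
the derived-parameter scale. The TEs are configurable placeholders: the
actual sequence timing is a per-site protocol choice.

What the phantom does **not** contain: k-space sampling, coil
sensitivities, motion, pulsatile flow, segmentation error (masks are
ground truth) or sub-pixel partial volume (edge pixels are in or out
wholesale). Passing closed-loop tests therefore demonstrates the
correctness of the estimators given the model, not robustness to those
real-data effects.

One structural caveat: the generator matches the *marginal* site-wise
distributions. The bilateral metabolic rate, a difference of two large
flow-extraction products, is extremely sensitive to the within-subject
joint distribution across IVC sites, which marginal summaries do not
constrain; at the marginal means the IVC extraction difference nearly
cancels. Bilateral records are therefore computed, flagged when
physically inconsistent, and compared between forms -- but no cohort-level
bilateral reference value is asserted.

## Fitting and numerical choices

* **T2 fit**: default is nonlinear least squares (Levenberg-Marquardt via
  `minpack.lm`) on the two-parameter model. The start is the better of
  the log-linear closed form and a coarse profiled grid (S0 eliminated in
  closed form over 80 log-spaced T2 values); the grid start keeps the
  optimizer out of the flat small-T2 region where the gradient vanishes,
  and the refined solution is kept only if it improves the start's sum of
  squares. Points are equally weighted; no Rician-floor correction term
  is applied (background suppression keeps the floor small), but a
  constant `offset` argument is available. `S0` is fit freely by default;
  `s0_fixed` pins it to the TE = 0 image if preferred. Non-decaying input
  is an explicit error, never a clamped value.
* **Flow**: ROI area is mask-pixel count times pixel area (consistent
  with the mask rendering; no sub-pixel contour integration). Velocities
  are averaged within a map; flows, not velocities, are averaged across
  maps. One shared mask serves all five interleaves. No phase
  unwrapping: the simulator guarantees `|v| < VENC` and real-data
  violations raise a warning.
* **Rounding**: only at the reporting layer (`round_for_report()`): flows
  and metabolic rates to the nearest ten, half away from zero;
  saturations to whole percent; T2 to whole ms.
* **Seeds**: every stochastic function takes a seed and restores the
  caller's RNG state; the pipeline derives per-stage, per-acquisition
  seeds from one root seed, so a run is a pure function of its config.

## Statistics

The condition effect per parameter and site is tested with a one-way
within-subject ANOVA (`stats::aov` with a subject error stratum;
F = MS(condition) / MS(error) on (k-1), (k-1)(n-1) degrees of freedom),
with subjects missing any condition excluded listwise. No sphericity
correction is applied by default -- the Greenhouse-Geisser epsilon is
available as an option and reported when used. Post hoc comparisons are
paired two-sided t-tests over all condition pairs with Bonferroni
adjustment implemented as multiply-then-cap, `min(1, 6p)` for four
stages; a pair with zero within-subject variance has no defined t
statistic and is reported as incomparable rather than p = 1. A residual
mean square at rounding-noise level (relative threshold 1e-12 of the data
variance) is reported as a degenerate design rather than an F of 0/0.

Uncertainty in the unilateral rate is propagated either to first order
(analytic partials) or by Monte-Carlo over independent Gaussian draws.
Because saturation enters only through the arteriovenous difference, an
SvO2 SD of s inflates the relative rMRO2 error by s/AVDO2 -- about 29%
for a 2-point saturation error at a 7-point normoxic AVDO2, which is why
the Fick estimate is far more sensitive to oximetry error than to a
comparable relative flow error.

## Problem sizes used by the tests and the acceptance script

Closed-loop identity runs a zero-noise, zero-SD cohort of 3 at a 48 x 48
matrix (exactness does not depend on n). Stochastic recovery uses 100
replicate studies of 10 subjects at a 32 x 32 matrix with one acquisition
per condition -- averaging identical-truth repeats adds nothing to a
coverage check. Power for the baseline-vs-moderate SvO2 contrast uses
500 truth-level replicates at n = 9 (one subject missing recovery, as in
the listwise-deletion scenario). The relaxometry bias check uses 1000
noisy decay curves per truth value at T2 = 71, 116 and 161 ms, SNR 50.
These sizes give Monte-Carlo standard errors well below the margins being
asserted.

## Known limitations

Whole-organ only (no cortex/medulla compartments); mono-exponential decay
(no multi-compartment or stretched-exponential models, no B1/flip-angle
correction); no eddy-current or background-phase correction; no per-pixel
T2 mapping (ROI means only, matching the analysis chain); the bundled
calibration is an anchored default, not a re-derivation of published
coefficients for a specific sequence; and the synthetic-data caveats
above.
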