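---
title: "Compensating cpRNFL thickness for ocular factors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compensating cpRNFL thickness for ocular factors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octcomp)
```

## The problem

Circumpapillary retinal nerve fiber layer (cpRNFL) thickness, measured by
OCT on a ring around the optic disc, is a candidate marker of
neurodegeneration: the papillomacular bundle thins in mild cognitive
impairment and Alzheimer's disease. The raw measurement, however, mixes
the axonal signal with ocular anatomy: larger discs push the measurement
ring closer to the disc where the layer is thicker, retinal vessels are
segmented as part of the layer, refractive error changes image scaling,
and scan quality biases segmentation. These nuisance contributions inflate
the between-eye variance and can mask a disease deficit of a few
micrometers.

`octcomp` implements a per-sector compensation of the 256-sector cpRNFL
profile and the machinery needed to ask whether compensation improves
disease discrimination.

## The compensation model

For each sector $s \in \{0, \dots, 255\}$, measured thickness in control
eyes is regressed on up to ten candidate covariate units: age, ethnicity
(one in/out unit of reference-coded indicators), refractive error, signal
strength, disc area, disc axis ratio, disc orientation, fovea distance,
fovea angle, and the sector's own vessel density. Subsets are scored by
the Gaussian AIC

$$\mathrm{AIC} = n \log(\mathrm{RSS}/n) + 2(k + 1),$$

with $k$ the number of mean parameters including the intercept and the
residual variance counted as one extra parameter; the subset minimizing
AIC is kept. Exhaustive enumeration (at most $2^{10}$ subsets per sector)
is the default; greedy forward selection is the fallback for larger
candidate sets or tight time budgets. Each sector is fit independently —
256 separate regressions, no spatial smoothing of coefficients (a
smoothing option was considered and deliberately left out of the default,
since nothing in the underlying procedure describes it).

Compensation subtracts the selected, centered effects:

$$\tilde y(s) = y(s) - \sum_k \hat\beta_k(s)\,\bigl(x_k - \bar x_k(s)\bigr),$$

where $\bar x_k(s)$ are training means. This form was chosen over
"predict-then-residualize" because it is mean-preserving: an eye at the
training means is returned unchanged, and the training-population mean
thickness is invariant per sector, so compensated values stay on the
familiar micrometer scale. The two forms differ only by a stored
constant. Two consequences used as tests: compensation is affine
equivariant (adding a constant to every profile adds the same constant to
the output), and with an empty candidate set it is the identity.

Training uses control-group eyes only; the model describes normal
anatomical variation and must not absorb disease effects. Age is kept as
a candidate by default but can be excluded (`candidates =` argument) for
longitudinal settings where age-related narrowing of vessels is itself of
interest. Vessel density couples locally (each sector to its own density)
with a `vd_mode = "quadrant"` switch for quadrant-mean coupling.

Covariates more than 6 training SDs from the mean are still compensated
but flagged as extrapolations. Rank-deficient designs (a constant
covariate) drop the offending unit with a warning. An exact fit
(RSS $= 0$) maps to a $-\infty$ AIC sentinel with an `exact_fit` flag.

## Feature extraction

The covariates come from en-face imagery:

* **Disc ellipse** — second-moment (covariance eigendecomposition) fit of
  the binary disc mask: area in mm², orientation as the angle between the
  horizontal axis and the major axis in degrees $[0, 180)$, ratio as the
  major/minor quotient. A near-circular mask (ratio within 0.5% of 1) has
  no meaningful major axis; its orientation is reported as 90° (the
  population mean orientation is near vertical) together with a
  `degenerate` flag.
* **Fovea geometry** — Euclidean disc-fovea distance and the signed angle
  to the horizontal through the disc center; negative angles mean the
  fovea lies inferior, matching the convention in which typical eyes have
  an angle around −8°.
* **Vessel density** — vessels are integrated over an annulus of
  diameters 3.28–3.64 mm (radii 1.64–1.82 mm) around the disc center,
  split into 256 equiangular wedges. "Density" is the vessel-positive
  area fraction of each wedge — a deliberate interpretation, since
  integrating "vessels in a band" could also mean calibers or crossings;
  area fraction is dimensionless, bounded and exactly reproducible by a
  per-pixel count, which the implementation must match bit-for-bit.
* **Macular composites** — from the 9 ETDRS sectors (ring radii fixed at
  the standard 0.5/1.5/3.0 mm): mGCC = mRNFL + mGCL + mIPL and
  mGC-IPL = mGCL + mIPL, per sector.

Sector indexing is fixed once: sector 0 starts at the temporal horizontal
meridian in right-eye orientation and indices proceed superiorly, so
temporal = sectors 0–63, superior 64–127, nasal 128–191, inferior
192–255. Left eyes are mirrored about the vertical axis before
extraction (an index reversal at the profile level), so nasal/temporal
semantics are shared across lateralities; laterality is kept as metadata.
All geometry is computed in millimeters, so results are invariant to the
pixel scale when inputs are scaled consistently.

## The synthetic cohort generator

No patient-level data are distributable, so the package ships a generator
that emulates the study conditions the analysis assumes; it is
first-class, tested code, and every acceptance-style check runs on it.

* **Covariates**: group-wise normal (or Bernoulli) draws matching the
  study's demographics table — e.g. controls with disc area 1.86 ± 0.39
  mm², disc ratio 1.13 ± 0.09, orientation 95.9 ± 33.2°, fovea distance
  4.52 ± 0.29 mm, fovea angle −8.06 ± 3.95°, refraction −1.11 ± 2.76 D,
  signal strength 7.56 ± 1.05, age 71.0 ± 4.7 y, 15% diabetes (32–34% in
  the impaired groups). Ethnicity is a 3-level categorical with default
  probabilities 0.7/0.2/0.1 (the source cohort is Asian without a stated
  composition; these are configurable, not claimed).
* **Clustering**: each subject contributes both eyes with probability
  `p_two_eyes` (default 0.5, matching the study's ~1.5 eyes/subject).
  Every eye-level latent draw is built as
  $\sqrt\rho\, z_\text{subject} + \sqrt{1-\rho}\, z_\text{eye}$ with
  `within_subject_rho = 0.6` by default — the source reports no
  between-eye correlation, so this is an exposed parameter, and the
  intraclass correlation of global thickness recovers it to ±0.1.
* **Thickness**: a smooth double-hump (superior/inferior) profile
  calibrated so the control temporal-quadrant mean is exactly 74 µm and
  the superior mean 115 µm at the reference age; a linear age slope of
  −0.2 µm/y; a temporally localized disease bump whose temporal-quadrant
  mean equals exactly the configured deficit (5 µm for both impaired
  groups, giving the reported 74 → 69 µm contrast); measured thickness
  adds the vessel contribution, covariate effects (disc area 10 µm/mm²,
  refraction 2 µm/D, signal strength 2.5 µm/unit, small
  diabetes/ethnicity shifts), a global eye offset (SD 6 µm), smooth
  eye-level Fourier shape variability (SD 7 µm), and white sector noise
  (SD 3.5 µm).
* **Severity**: all disease deficits (cpRNFL, vessel density, macular)
  are scaled by a subject-level severity factor
  $\max(0, 1 + 0.3\,z)$. Without shape variability and severity, quadrant
  contrasts would be deterministic given the group and any score model
  would separate groups perfectly — an early draft did exactly that, and
  the fix is what makes the synthetic cohorts behave like the study
  (measured cpRNFL AUC ≈ 0.69 rather than 1.0).
* **Vessel confound**: measured thickness includes
  `vessel_coupling` × (the eye's density deviation from the population
  profile), so the coupling adds variance and correlation without
  shifting the calibrated means. The default coupling of 4.2 µm per
  density unit was fixed by a one-time simulation sweep so that the
  correlation between mean vessel density and mean measured thickness
  across eyes is ≈ 0.20 (8 sweeps × 1800-subject cohorts: range
  0.17–0.24), emulating the reported weak confound (r ≈ 0.21) that
  compensation should remove (reported r ≈ −0.08 afterwards).
* **Images**: `render_enface()` draws the disc as a filled ellipse, the
  fovea as a landmark at the configured distance/angle, and the vessels
  as one radial spoke per sector whose caliber is proportional to that
  sector's density (constant through the 3.28–3.64 mm band, tapering
  outside). A free-branching random tree was considered and rejected:
  branching cannot guarantee the annular sector densities that the
  extraction module must recover, and visual realism is a non-goal. The
  caliber-per-density calibration is written to the image sidecar so
  extracted area fractions convert back to cohort density units.

What the generator does *not* emulate: OCT speckle and B-scan physics,
choroidal/outer-retina structure, comorbid eye disease, spatially
structured segmentation artifacts, or non-Gaussian covariate tails.
Passing tests on synthetic cohorts therefore demonstrate the internal
consistency and statistical behavior of the pipeline under the study's
covariate structure — not clinical performance on real scans.

## Diagnostics

Score models are multivariable logistic regressions fit by
Newton–Raphson/IRLS with a ridge of $10^{-8}$ on the Hessian — numerical
stabilization only, with no effect at reporting precision; perfect
separation is detected and returned at the iteration cap with a warning
rather than an error, since separated in-sample scores are still valid
ROC inputs. The five-model menu mirrors the study's comparison table:
measured cpRNFL quadrants; vessel-density quadrants; macular
mRNFL + mGCL + mIPL sectors; compensated quadrants plus ocular factors;
and the combined model (compensated + factors + mGCC).

AUC is the midrank Mann–Whitney estimator (ties count ½), identical to
the all-pairs count. Sensitivity at 80% specificity is read off the
empirical ROC without interpolation: the maximum sensitivity among
thresholds with specificity ≥ 0.80 — reproducible without smoothing
assumptions. Paired AUCs are compared with the DeLong placement-value
test at eye level (the classical form treats eyes as independent);
because fellow eyes are correlated, confidence intervals are also
produced by a subject-clustered bootstrap that resamples subjects with
their eyes and refits the score model on each resample (percentile
interval, default B = 2000; resamples on which the statistic is
undefined, e.g. single-class draws, are redrawn and counted). In-sample
(apparent) AUC is the default, matching the comparison being reproduced;
subject-level cross-validation can be layered on by the user but is not
wired in.

Post-hoc power uses the unpooled two-sample normal approximation
$z = |\mu_1-\mu_2| / \sqrt{s_1^2/n_1 + s_2^2/n_2}$,
$\text{power} = \Phi(z - z_{1-\alpha/2}) + \Phi(-z - z_{1-\alpha/2})$.
On the inner-retina summary (33 ± 4, n = 170 vs 36 ± 5, n = 55, α = 0.05)
this yields 98.2%; the unpooled form was chosen because it reproduces that
conventional figure exactly, and a pooled-SD variant is available behind a
flag. For the cpRNFL summary
(69 ± 12 vs 74 ± 15) the approximation gives ≈ 61%, not the 66.4%
produced by the original authors' online calculator — the calculator's
internals are unknown, and that figure is deliberately not targeted.

## Numerical choices and degenerate inputs

* AIC subsets are solved from a per-sector bordered Gram matrix, so the
  exhaustive scan is $O(2^K k^3)$ per sector with no re-decomposition of
  the design; singular subsets are skipped.
* Logistic features are internally centered/scaled for conditioning;
  coefficients are mapped back to the original scale.
* `delong_test` on identical score vectors (zero variance of the
  difference) returns p = 1 with a `degenerate` flag.
* Annulus wedges with no pixels at very coarse scales return `NA` with a
  warning rather than failing, so the brute-force oracle remains exactly
  reproducible on small grids.
* All randomness flows from explicit integer seeds: a cohort
  configuration, a bootstrap call, and the pipeline are each deterministic
  given their seed, and reruns are bit-identical.

## Problem sizes

The shipped checks run the generator at the study's size (55/108/62
subjects, ≈ 330 eyes) for diagnostic comparisons, 300 control subjects
for parameter-recovery runs (20 seeds), a 3600-subject cohort for the
decorrelation check, 2000 replicates for the DeLong size check, and 200
replicates × B = 500 for bootstrap coverage — sizes chosen so each
property is measured with comfortable Monte-Carlo margin while a full run
of the suite stays conveniently short.

## Known limitations

* The compensation coefficients of the original instrument-specific
  models are not published and are not reproduced; only the method is.
* Whether the original vessel-density measure is an area fraction is not
  stated; the area-fraction choice is documented above.
* DeLong p-values at eye level ignore fellow-eye correlation; the
  clustered bootstrap is reported alongside for that reason.
* The in-sample AUCs of richer models (27 macular features) are
  optimistic by construction; the comparison reproduces apparent, not
  cross-validated, performance.
* The generator's effect sizes are calibrated to the reported group
  summaries; it cannot validate claims beyond the structure put into it.
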