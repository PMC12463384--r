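---
title: "Methods: lesion morphometry, clearance and threshold prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lesion morphometry, clearance and threshold prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermavol)
```

## The measurement problem

Basal cell carcinomas treated with photodynamic therapy change size by
fractions of a millimeter between visits — far below what a ruler or 2D
photograph resolves. Stereo photogrammetry reconstructs the skin surface as
a dense elevation field; the analysis questions are then geometric: how
much lesion material sits above (and below) the surrounding skin surface,
how does that change over a five-visit treatment course, and does the
baseline size predict whether the lesion will clear?

`dermavol` implements that analysis on raster height maps: a regular grid
of elevations (mm) at known pixel spacing. How the grid was produced
(stereo matching, structured light, profilometry) is out of scope; the
package starts where the surface ends.

## Morphometry model

**Reference plane.** Skin is locally approximated by a plane
$z = ax + by + c$, fitted by ordinary least squares to the cell centres of
a background ROI drawn on normal skin. Least squares is a choice — vendor
systems do not document their plane — but it is reproducible, closed-form,
and its residual RMS doubles as a data-quality figure. The fit needs at
least three non-collinear background cells; a sliver ROI one cell wide is
rejected.

**Volumes.** With plane residuals $r_i = z_i - (ax_i + by_i + c)$ over
lesion-ROI cells of area $\Delta^2$:

$$V^+ = \Delta^2 \sum_i \max(r_i, 0), \qquad
  V^- = \Delta^2 \sum_i \min(r_i, 0),$$

net volume $= V^+ + V^-$, and the absolute volume
$\mathrm{3DAbsVol} = V^+ + |V^-|$. Absolute volume is the primary size
measure because ulcerated lesions carry burden below the plane: a crater
and a nodule should not cancel.

**Heights.** Maximum height is the largest positive residual (floored at
0, so a purely ulcerated lesion reports 0 rather than a negative height).
Average height $\mathrm{3DAvHt} = \mathrm{3DAbsVol}/A$ with $A$ the
*projected* polygon area (shoelace formula). Projected rather than 3D mesh
area is deliberate: dividing a volume by a footprint gives a physically
interpretable mean thickness, and for near-flat lesions the two areas
coincide. Note the consequence: because clinicians outline the ROI outside
the visible border, $A$ exceeds the lesion footprint and 3DAvHt
underestimates the true mean cap height; the same effect is visible in
clinical report tables where volume/avht ratios imply ROI areas much larger
than the printed diameter ellipse.

**Diameters.** Major diameter is the maximum Feret diameter — the largest
vertex-pair distance, computed on the convex hull; the perpendicular
diameter is the polygon's extent orthogonal to the major axis. A brute
force $O(n^2)$ pair scan is kept in the tests as the oracle.

**Roughness.** Implemented as Rq, the RMS plane residual over the ROI —
the standard surface-metrology default. Vendor "roughness" definitions
vary; Rq is one function swap away if a different convention is needed.

**Cell membership.** A cell belongs to an ROI iff its centre lies inside
the polygon (even-odd rule). This makes every integral an exact finite sum
that a brute-force oracle can reproduce bit for bit, and makes convergence
behaviour transparent: hemisphere volume error shrinks monotonically as
spacing halves (verified in the tests at 0.16 → 0.02 mm).

## Phantom calibration

Physical phantoms (epoxy half-sphere beads, density 1.2 mg/mm³) tie the
measurement chain to ground truth: actual volume = mass/density, and the
calibration is the OLS line of measured 3DAbsVol on actual volume. Two
facts matter:

- A vendor stereo pipeline was reported to measure roughly half the true
  phantom volume — a property of the mesh reconstruction, not of volume
  integration. The package's own end-to-end phantom run (generate
  hemisphere → fit plane → integrate) yields slopes in [0.95, 1.02],
  asserted in the acceptance tests: grid integration adds no such bias.
- Calibration is reported, never applied automatically. The clearance and
  prediction analyses depend on *relative* changes, which a linear
  measurement bias does not disturb. `apply_calibration()` exists for users
  who need absolute scales.

## Clearance rule

Background ROIs on normal skin never read zero — micro-texture integrates
to ~0.4–0.8 mm³. The background model takes the per-lesion readings,
computes sample mean and SD (n−1), and sets the clearance threshold at
mean + k·SD.

Choices, and why:

- **k = 1.** The worked clinical example (readings 0.44, 0.59, 0.73 mm³ →
  0.59 ± 0.15) is classified "cleared at V4" with k = 1 (V4 volume 0.73 ≤
  0.73 threshold at 2 d.p.; 0.73 ≤ 0.7317 at full precision), and that is
  the only fully worked case available. Whether the original analysts used
  mean + 1·SD, 2·SD or visual judgment is not documented; k is a parameter.
- **≤, not <.** A value exactly at threshold clears — required by the
  worked example under 2-decimal rounding.
- **Sustained clearance.** The earliest qualifying visit among V3–V5 must
  be followed only by sub-threshold visits. Lesions that dip below
  threshold and regrow are partial responders, not cleared.
- **V3–V5 only.** V1 is baseline and V2 precedes any treatment effect; a
  sub-threshold V1/V2 value never produces a call. Lesions missing any
  visit are excluded upstream (with a reason) rather than imputed.

## Threshold prediction

Baseline (V1) size predicts response: *predicted responder ⇔ predictor ≤
t*. The orientation deserves a note: thin/small lesions are the ones that
clear, which the data and the headline result (baseline average height
< 0.15 mm predicts complete response) both support; one sentence in the
source literature states the opposite direction and is taken to be an
erratum.

Sensitivity is computed over actual responders (cleared by V5),
specificity over nonresponders. The sweep evaluates every distinct
predictor value plus midpoints between consecutive values; with the ≤
orientation, sensitivity is non-decreasing and specificity non-increasing
in t, so |sens − spec| has a well-defined crossing. The **operational
threshold** is the candidate minimising |sens − spec|, ties broken toward
the smaller threshold (the conservative side: fewer predicted responders).

`exclude_aggressive()` removes micronodular and infiltrative lesions —
assumed pre-identified by biopsy and not sent to PDT in practice. These
subtypes are the mechanism behind poor specificity: they can be thin yet
refuse to clear, so they sit on the "predicted responder" side of any
height threshold as false positives. Removing them raises specificity, a
property the tests verify on cohorts where thin aggressive nonresponders
are planted.

`depth_correlation()` regresses baseline average height on histological
depth (OLS, Pearson r, mean ratio). Surface relief runs ~10–20% of true
depth; the package treats the ratio as a generator parameter (default
0.15) rather than a biological constant.

Wilson confidence intervals are deliberately *not* attached to the
reported operating points: the source analysis reports point estimates,
and dressing stochastic sweep output in intervals it never had would
suggest a precision claim the data do not make.

## The synthetic world

Every stage is testable offline because the generator plants known truth:

- **Surfaces.** Skin = plane (optional tilt) + i.i.d. Gaussian per-pixel
  noise. Real skin texture is spatially correlated and anisotropic; nothing
  here claims otherwise — this is the simplest model that exercises plane
  fitting and noise propagation. Lesions are spherical caps, ellipsoidal
  caps, or caps with a central crater dipping below the plane (raised-edge
  ulcerated morphology). Truth volumes come from adaptive 1D radial
  quadrature — exact to ~1e-10 and independent of the grid, so grid
  integration is tested against genuinely external values.
- **Trajectories.** Five-visit multiplier profiles for four archetypes:
  complete responder (the worked example's rise-then-fall shape, default
  baseline 9.17 mm³), partial regrower (dips, then returns), nonresponder
  (steady growth), thin aggressive nonresponder (small, flat, growing).
  Visit volumes are floored at the background level; background readings
  are |N(0.59, 0.15)| mm³, matching the observed background scale.
- **Cohorts.** Subtype mixture follows the observed distribution
  (superficial 31%, nodular 44%, micronodular 15%, infiltrative 5%, other
  7% — printed percentages summing to 102%, normalised here to sum to 1).
  Baseline average height is N(0.15, 0.06) mm truncated at 0.01; responder
  probability is logistic, $p = \sigma((0.15 - \mathrm{avht})/s)$ with
  scale $s = 0.05$ mm. Two deliberate choices: the height distribution is
  *symmetric about the logistic midpoint*, which makes the population
  sensitivity and specificity curves cross exactly at the midpoint — so
  "the sweep recovers 0.15 mm" is a well-posed recovery test, not a lucky
  coincidence; and $s$ = 0.05 mm puts the operating-point accuracy in the
  70–85% band observed clinically (a sharper logistic would make the
  prediction problem unrealistically easy). Depth = avht/0.15 + N(0, 0.15)
  mm. Baseline absolute volume = avht × lognormal ROI area
  (median 80 mm², sdlog 0.5), matching clinical ROIs of tens to a couple
  of hundred mm².
- **Raw-cohort accounting.** `simulate_raw_cohort()` adds non-BCC and
  incomplete-visit lesions (defaults 40 + 49 on top of 122 analyzable,
  the study's 211 → 122 profile) so the reader's exclusion report is
  exercised end to end.

What a green test establishes — and what it does not: the pipeline
recovers planted truth under the generator's assumptions (uncorrelated
noise, radially symmetric lesions, exactly logistic response). It does not
establish performance on real reconstructions with hair occlusion,
correlated texture, or irregular lesion geometry, none of which the
generator emulates.

## Numerical choices and degenerate inputs

- All lengths mm, areas mm², volumes mm³; x right, y down, origin at the
  grid corner, cell centres at (i − ½)·spacing.
- Nodata cells are excluded from every integral and their count reported.
- ROI constructors reject self-intersecting or zero-area polygons;
  overlap between lesion and background ROIs is an error (vertex
  containment or proper edge crossing).
- Plane fits, calibration and depth regressions use QR-based `lm`; tests
  pin them to explicit normal-equation oracles at 1e-9.
- `background_stats()` requires ≥ 2 readings (sample SD undefined);
  `classify_clearance()` requires exactly 5 non-missing visits;
  `sens_spec()` errors on an empty class rather than returning NaN.
- Determinism: every generator takes a seed (`withr::with_seed`, so the
  global RNG state is untouched); the pipeline derives per-stage seeds from
  one master seed and its outputs are byte-identical across runs.

## Known limitations

- Projected (not 3D mesh) surface area; see the morphometry note above.
- The vendor's exact roughness and max-height definitions are unknown; Rq
  and max positive residual are documented stand-ins.
- The Gaussian skin texture is a placeholder, not a skin model.
- Clearance-by-threshold inherits the background ROI's quality: a
  background region containing lesion tissue inflates the threshold.
- The cohort-level clinical proportions (41/58/70% cumulative clearance;
  69/53 and 81/62 operating points) require the original per-lesion
  measurement table, which is not publicly deposited; the package
  reproduces the *procedures* and validates them on synthetic cohorts
  instead of asserting those numbers.
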