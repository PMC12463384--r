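# dermavol

Quantitative 3D surface morphometry of skin tumors, and prediction of
photodynamic-therapy (PDT) response from baseline lesion size.

Basal cell carcinoma (BCC) lesions treated with topical PDT (5-ALA + blue
light) shrink, regrow or persist over a multi-visit treatment course.
Stereo-photogrammetric cameras can reconstruct the skin surface at
sub-millimeter resolution; `dermavol` implements the downstream analysis
for researchers working with such reconstructions (represented here as
raster height maps):

- **ROI morphometry.** A reference plane `z = a·x + b·y + c` is fitted by
  least squares to a background region of normal skin. Within the lesion
  ROI, cut-and-fill integration of the plane residuals gives the positive
  volume `V⁺ = Σ max(zᵢ − pᵢ, 0)·Δ²` and negative volume
  `V⁻ = Σ min(zᵢ − pᵢ, 0)·Δ²` (Δ = pixel spacing). The package's primary
  size measures are the **absolute volume** `3DAbsVol = V⁺ + |V⁻|` and the
  **average height** `3DAvHt = 3DAbsVol / A`, with `A` the projected ROI
  area. Feret diameters and RMS roughness (Rq) complete the report.
- **Phantom calibration.** Half-sphere beads of known mass m and density ρ
  (volume m/ρ) calibrate the measurement chain via OLS of measured on
  actual volume. The fit is reported, never silently applied.
- **Clearance classification.** Background readings define a threshold
  `mean + k·SD` (k = 1 by default). A lesion is *cleared at V3/V4/V5* at the
  earliest post-treatment visit whose absolute volume is at or below
  threshold and stays there through V5; otherwise *not cleared*.
- **Response prediction.** Sweeping a baseline size threshold t
  (predicted responder ⇔ predictor ≤ t) yields sensitivity/specificity
  curves; the **operational threshold** is the t where they are
  approximately equal (argmin |sens − spec|). Aggressive subtypes
  (micronodular, infiltrative) can be excluded, and baseline average height
  is regressed on histological depth (heights run ~10–20% of true depth).
- **Synthetic data.** Spherical/ellipsoidal caps and ulcerated lesions on
  noisy tilted skin, hemispherical phantoms with analytic volumes,
  archetypal five-visit trajectories, and full cohorts with planted
  responder status — so the entire pipeline is testable without clinical
  images.

## Worked example

```r
library(dermavol)

# An ulcerated lesion (r = 2 mm, rim height 0.5 mm, ulcer 0.4 mm deep)
# on noisy skin, with lesion and background ROIs:
sc <- make_lesion_scene(
  lesion_shape("cap_with_ulcer", radius_mm = 2, height_mm = 0.5, ulcer_depth_mm = 0.4),
  skin_params(grid_size = 160, pixel_spacing = 0.05, noise_sd = 0.01, seed = 7)
)
analyze_roi(sc$map, sc$lesion_roi, sc$background_roi)
#>   surface_area_mm2 major_diameter_mm perpendicular_diameter_mm
#>             15.204               4.4                       4.4
#>   positive_volume_mm3 negative_volume_mm3 net_volume_mm3 absolute_volume_mm3
#>                 2.059              -0.448          1.611               2.507
#>   max_height_mm average_height_mm roughness_mm
#>           0.405             0.165        0.206
```

The ulcer shows up as a negative volume, so the absolute volume (2.507 mm³)
exceeds the net volume (1.611 mm³): material both above and below the skin
plane counts toward lesion burden.

```r
# Clearance call for a five-visit trajectory against its background:
bg <- background_stats(c(0.44, 0.59, 0.73))
bg
#> <background_model> mean 0.587 +/- 0.145 mm^3 (n = 3); threshold mean + 1 SD = 0.732 mm^3
classify_clearance(c(9.17, 11.76, 5.73, 0.73, 0.70), bg)
#>   status  cleared_visit threshold_mm3
#>   cleared             4         0.732
```

The lesion grew before the first treatment, shrank after it, and reached
the normal-skin background level at visit 4, staying there at visit 5 —
cleared at V4.

```r
# End-to-end synthetic cohort at the study scale:
res <- run_pipeline(pipeline_config(params = cohort_params(n_lesions = 122), seed = 42))
res
#> <pipeline_result> 122 analyzable lesions; cleared by V3/V4/V5: 36% / 48% / 56% (NC 44%)
#>   predictor     operational_threshold sensitivity specificity     n cohort
#> 1 absvol_v1_mm3                10.6         0.574       0.574   122 all
#> 2 avht_v1_mm                    0.148       0.691       0.685   122 all
#> 3 absvol_v1_mm3                10.5         0.566       0.556    98 no_aggressive
#> 4 avht_v1_mm                    0.147       0.679       0.689    98 no_aggressive
```

The sweep recovers the planted 0.15 mm average-height midpoint (estimate
0.148 mm) with sensitivity ≈ specificity ≈ 69% at the operating point;
average height separates responders better than absolute volume, mirroring
the clinical finding. `autoplot()` methods visualise height maps,
calibration fits, threshold sweeps and depth correlations; `tidy()` /
`glance()` return the underlying tables.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the reportable quantity from scratch with the installed package
— it builds the background model from the worked example's three normal-skin
readings, classifies the five-visit volume trajectory with the sustained
background-threshold rule, and writes the first clearance visit as JSON.

See `vignettes/dermavol-methods.Rmd` for the full model description,
parameter choices and limitations.
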