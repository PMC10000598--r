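---
title: "Methods: markerless posture analysis from depth captures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: markerless posture analysis from depth captures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

posturekit reconstructs a 28-point body skeleton from depth-frame
sequences of a standing, clothed subject captured in three poses (front,
side, back) and derives six clinical posture outcomes.  This vignette is
the package's own account of the model, its assumptions, the tunable
parameters, and what the synthetic validation does and does not establish.

## The measurement model

A structured-light depth camera at a fixed distance returns per-pixel
z-depth in millimetres.  The subject frame is x = anatomical right,
y = up from the floor, z = anterior.  The front view is horizontally
mirrored (the viewer's right is the subject's left); the back view is
not; the side view places the camera on the subject's right, so the
subject's anterior axis maps to the image horizontal and the camera depth
axis measures the mediolateral coordinate.  This convention is what makes
"negative = left raised / tilted left" a testable statement.

The pipeline per synchronized frame triple:

1. **Silhouette** — a pixel is foreground when the background reference
   depth exceeds the frame depth by more than `tau` (default 100 mm) and
   the frame depth lies within ±600 mm of the nominal capture distance.
   The largest 4-connected component is kept and interior holes (depth
   dropout, enclosed limb gaps) are filled.  Filled pixels carry no
   usable geometry and are excluded from all landmark scans.
2. **Superpixels** — SLIC restricted to the mask: grid-seeded centers at
   step `S = sqrt(area/K)` (default `K = 400`), assignment within 2S
   windows minimizing `D^2 = d_depth^2 + m^2 (d_xy/S)^2` with depth
   rescaled to [0, 100] over the mask and compactness `m = 20`, ten
   center updates, then a connectivity pass.  The recorded objective is
   the summed squared distance; the per-pixel argmin is identical under
   the square root, and this form is provably non-increasing.
3. **Body parts** — twelve classes (head, neck, torso, pelvis, and
   left/right upper arm, forearm+hand, thigh, shank+foot) predicted per
   superpixel from six features: bbox-normalized centroid, mean depth
   minus the silhouette median, area fraction, second-moment elongation,
   and centroid height fraction.  The classifier is a maximum-margin
   linear model (per-class weight vector and bias) trained by seeded
   mini-batch stochastic subgradient descent on the L2-regularized
   *multiclass* hinge loss, returning the averaged iterate.  A one-vs-rest
   decomposition was tried first and rejected: the pelvis and neck
   regions are slabs sandwiched between neighbours, representable by
   argmax-of-linear scores but not separable by any independent binary
   linear classifier (one-vs-rest pelvis recall was below 30% even for a
   well-tuned reference implementation; the coupled hinge reaches ~95%
   held-out accuracy).  Classes are reweighted by capped inverse
   frequency so small parts are not drowned out.
4. **Landmark calibration** — each of the 28 landmarks has a registry
   entry naming its source view, part class, scan band, fit plane and
   extremum rule.  Scan rules back-project the part's pixels and fit a
   quadratic to a depth point cloud: the shoulder line is the
   full-silhouette top contour referenced to the head-centroid midline
   (classifier-free, the most stable structure in the upper body); the
   iliac crests are the vertex of a quadratic fit to the lateral edge
   profile of the pelvis region; limb joints come from straight-line
   axis fits of per-row means anchored at the lateral silhouette edge
   (so a misclassified strip of the adjacent limb cannot drag the axis
   when the knees touch).  Depth at tangential silhouette edges is
   estimated from the intercept of z² regressed on the in-plane offsets
   (on a quadric surface z² is exactly quadratic there), and
   mid-plane landmarks average the front- and back-view estimates so the
   clothing and noise-folding biases cancel.  The patella height is read
   from the zero crossing of the thigh-versus-shank classifier score
   margin along the limb (sub-superpixel precision) plus the fixed
   body-model offset between the visible depth-buffer transition and the
   joint center, `sqrt(r_thigh² − r_shank²) − (r_thigh − r_shank)`
   scaled by the measured shank half-width.  The depth coordinate of
   every landmark is corrected toward the bone surface by a per-part
   clothing estimate: the 95th percentile of the residual of
   superpixel-mean depth against a smooth quadratic trend, computed over
   the central band of the part (where the limb's own curvature does not
   inflate the residuals) and capped at 25 mm.
5. **Averaging** — the 28 points are located in every frame of the 2–3 s
   window; per landmark, frames with fit RMSE above 25 mm are discarded
   and the survivors (at least `min_valid = 5`) are arithmetically
   averaged.

## The six outcomes

With L/R landmark pairs and the sign convention "negative = left raised
or tilted left":

* asymmetric clavicle height: `atan2(y_R − y_L, x_R − x_L)` over the
  highest clavicle points, degrees;
* pelvic obliquity: the same elevation angle over the iliac-crest
  midpoints, plus the signed height difference `y_R − y_L` in mm.  The
  outcome is implemented as a *vertical* asymmetry although one reading
  of the outcome list calls it a horizontal distance: pelvic obliquity
  is clinically a frontal-plane tilt, and the left-raised sign rule is
  only meaningful for a height difference.  The literal reading is
  available behind `compute_posture(variant = "literal")`, without
  endorsement;
* Q angles: 180° minus the angle between the ASIS→patella line and the
  patella→tibial-tuberosity line in the coronal plane, signed positive
  for lateral (valgus) deviation on either limb;
* C7–CSL: the signed *horizontal* offset of the C7 center from the
  vertical central sacral line, mm (and its inclination in degrees).  A
  plumbline offset is horizontal by definition — the mm/deg pair mirrors
  how such devices report it;
* forward head posture: sagittal inclination of the C7→ear-canal line
  from the vertical, positive anterior.

## The synthetic subject

The generator is first-class, tested code: a capsule-union humanoid whose
28 ground-truth landmarks are placed on the *visible skin surface* so a
depth camera can observe them without systematic bias, then deformed so
that each of the six outcomes, recomputed from the placed points by
`compute_posture()`, equals the requested value to 1e-9 (the knee
position solves the signed Q angle by root finding with the ankle fixed
under the hip).  Rendering z-buffers the capsules against a wall at the
background distance; clothing is a smooth seeded field that moves torso
and limb surfaces up to `clothing_amplitude` (default 15 mm) *toward* the
camera; i.i.d. Gaussian depth noise (default 5 mm) is added per frame to
body pixels; 20 frames per view model 2–3 s at ~8 fps.

Between-subject variation reproduces the study population's descriptive
statistics (means, SDs, and truncation at the printed ranges):
clavicle −1.0 ± 1.6°, pelvic obliquity 0.7 ± 1.6°, right Q 0.9 ± 7.9°,
left Q −3.1 ± 4.0°, C7–CSL −3.0 ± 13.3 mm, FHP 7.9 ± 6.3°, with stature
1634 ± 80 mm and ±10% girth.  The retest jitter default
(`posture_jitter_sd = 0.7`, each parameter's own unit) was chosen a
priori so that, with those between-subject SDs, the implied true ICC for
the least-variable parameters is ≈ 0.75–0.8, matching the published
qualitative reliability; it was not adjusted after seeing test output.

What the generator does **not** emulate: garment folds and drape
dynamics, body-shape statistics beyond girth scaling, hair, self-occlusion
from non-standard poses, multi-path and edge artifacts of real
structured-light sensors, and floor reflections.  A green end-to-end test
therefore establishes that the geometry pipeline is correct and robust to
the modelled noise and clothing — not that the device would reach the
same accuracy on patients.

## Numerical choices

* Quadratic fits use QR least squares; the vertex is reported only when
  |a| > 1e-6 mm⁻¹, otherwise the fit is flagged flat.  Limb and trunk
  *axes* use a straight-line model: a quadratic would amplify row noise
  at the joint ends of the scan band and tilt the short patellar-tendon
  vector by several degrees.
* Landmark scans trim stray superpixels (beyond 4 MADs of the part's
  median position) and reject scan rows pulled off the axis trend.
* Camera defaults (640×480, f = 580 px, subject at 2500 mm, wall at
  4000 mm, optics 900 mm above the floor) are plausible fixtures for a
  consumer sensor, not claims about any device.
* The ICC is fixed to the two-way random-effects, absolute-agreement,
  single-measures form with F-based 95% bounds; the form tag is recorded
  in every result.  Correlation bands are applied to |r| after rounding
  to two decimals.  Covariate adjustment of validity tables is out of
  scope and flagged in the report metadata.
* `paired_t` returns t = 0, p = 1 for exactly identical inputs and
  errors on constant non-zero differences.

## Known limitations

Landmark depth at tangential edges remains the least accurate coordinate
(±10–15 mm after the front/back symmetrization); it does not enter any of
the six outcomes.  Subjects whose shanks overlap in the image (extreme
opposite Q angles) are rejected by the generator as infeasible rather
than rendered.  The part classifier is trained on the generator's own
population; applying it to differently proportioned subjects would need
retraining via `train_part_classifier()`.
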