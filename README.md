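# posturekit

Markerless postural analysis from consumer depth-camera captures, in R.

Clinicians screening for postural asymmetry (somatic dysfunction,
scoliosis follow-up, pre/post manual-therapy assessment) need repeatable,
radiation-free measurements.  posturekit implements the full analysis
chain of a depth-camera posture device: sequences of 16-bit depth frames
of a standing, clothed subject (front, side and back poses plus a
background reference) are turned into a 28-point body skeleton and six
clinical outcomes, together with the agreement statistics used to
validate such devices against radiographic references.

**Pipeline.**  Background subtraction yields the subject silhouette;
SLIC superpixels (localized k-means over position + depth, distance
`D² = d_depth² + m²·(d_xy/S)²`) partition it; a maximum-margin linear
classifier labels twelve body parts; each landmark is calibrated by a
least-squares quadratic fit `z = a·x² + b·x + c` to the depth point cloud
of its scan region (vertex, topmost or midline rule), corrected for
clothing, computed per frame over the 2–3 s capture, gated by fit RMSE
and averaged.

**The six outcomes** (negative = left raised / tilted left):

| outcome | definition | unit |
|---|---|---|
| asymmetric clavicle height | elevation angle of the highest-clavicle pair | deg |
| pelvic obliquity | elevation angle / height difference of the iliac-crest midpoints | deg, mm |
| right / left Q angle | ASIS–patella vs patellar-tendon line, + = valgus | deg |
| C7–CSL | horizontal offset of C7 from the central sacral vertical line | mm, deg |
| forward head posture | inclination of the C7–ear-canal line from vertical | deg |

A synthetic capture generator (capsule-union humanoid with exact
ground-truth skeleton, clothing offset field, depth noise, test–retest
jitter, population statistics of a clinical cohort) makes every stage
testable end to end; `icc_single()` (ICC(2,1) with 95% CI),
`pearson_corr()`, `paired_t()` and the qualitative banding rules cover
the reliability/validity statistics.

## Worked example

```r
library(posturekit)

camera <- camera_model()                       # 640x480, subject at 2.5 m
p <- subject_params(clavicle_asym_deg = -2, pelvic_oblique_deg = 1.5,
                    q_right_deg = 5, q_left_deg = -3,
                    c7_csl_mm = -13, fhp_deg = 7.9)
gt <- build_skeleton(p)                        # exact ground truth
session <- render_session(gt, camera, n_frames = 20, seed = 7)

clf <- train_part_classifier(seed = 1)         # ~10 s, cached by default_classifier()
res <- analyze_session(session, clf)
res$parameters
```

Output actually printed by the above:

```
<posture_parameters>
  asymmetric clavicle height:   -1.77 deg
  pelvic obliquity:              1.92 deg (11.9 mm)
  Q angle right / left:          4.32 / -2.57 deg
  C7-CSL:                       -14.3 mm (-1.84 deg)
  forward head posture:          7.61 deg
```

Every estimate lands within about half a degree (or a few mm) of the
requested ground truth; over 20 random subjects at default noise and
clothing the median absolute error is below 1° per angle parameter and
below 2 mm for C7–CSL.

The command-line workflow mirrors the library
(`exec/posturekit simulate | train-parts | analyze | retest | validate |
dump-config`), e.g.

```sh
Rscript exec/posturekit simulate --seed 3 --frames 20 --out session/
Rscript exec/posturekit analyze --session session/ --out report/
```

`report/` then holds `skeleton.json` (28 named points, mm),
`parameters.csv` (six outcomes) and overlay PNGs.

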