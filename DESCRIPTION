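Package: posturekit
Title: Markerless Postural Analysis from Depth-Camera Captures
Version: 0.1.0
Authors@R:
    person("posturekit", "developers", email = "posturekit@example.org",
           role = c("aut", "cre"))
Description: Reconstructs a 28-point body skeleton from sequences of depth
    frames (front, side and back views) of a standing, clothed subject and
    derives six clinical posture parameters: asymmetric clavicle height,
    pelvic obliquity, bilateral Q angles, C7 offset from the central sacral
    line, and forward head posture.  The pipeline follows the markerless
    depth-camera approach: background subtraction to a silhouette, SLIC
    superpixel segmentation, maximum-margin body-part labelling, and
    per-landmark quadratic fits to depth point clouds averaged over the
    capture window.  Includes a synthetic clothed-humanoid depth renderer
    with known ground truth, and the agreement statistics (ICC(2,1) with
    confidence intervals, Pearson correlation, paired t-tests and
    qualitative reliability bands) used to validate such devices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
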