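# Shared fixtures, all generated in code.  The classifier bundle and the
# small rendered session are cached for the whole test run.

pk_env <- new.env(parent = emptyenv())

pk_camera <- function() camera_model()

pk_classifier <- function() {
  if (is.null(pk_env$clf)) pk_env$clf <- default_classifier(seed = 1)
  pk_env$clf
}

pk_params <- function(...) {
  subject_params(clavicle_asym_deg = -2, pelvic_oblique_deg = 1.5,
                 q_right_deg = 5, q_left_deg = -3, c7_csl_mm = -13,
                 fhp_deg = 7.9, ...)
}

# one default-noise session of the reference subject, 6 frames per view
pk_session <- function() {
  if (is.null(pk_env$sess)) {
    pk_env$gt <- build_skeleton(pk_params())
    pk_env$sess <- render_session(pk_env$gt, pk_camera(), n_frames = 6,
                                  seed = 42)
  }
  pk_env$sess
}

pk_truth <- function() {
  pk_session()
  pk_env$gt
}

# clean (no clothing, no noise) single-frame session
pk_clean_session <- function() {
  if (is.null(pk_env$clean)) {
    pk_env$clean_gt <- build_skeleton(pk_params(clothing_amplitude = 0,
                                                noise_sd = 0))
    pk_env$clean <- render_session(pk_env$clean_gt, pk_camera(),
                                   n_frames = 1, seed = 9)
  }
  pk_env$clean
}

# silhouette / superpixels / labeling for one view frame
pk_view <- function(session, view, i = 1, clf = pk_classifier()) {
  f <- session$frames[[view]][[i]]
  sil <- extract_silhouette(f, session$background[[view]],
                            camera = session$camera)
  sp <- slic_segment(sil, f)
  feat <- extract_features(sp, f, sil)
  lab <- predict_parts(clf[[view]], feat)
  list(frame = f, sil = sil, sp = sp, feat = feat, lab = lab)
}
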