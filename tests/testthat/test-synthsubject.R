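test_that("ground-truth skeleton reproduces the requested parameters exactly", {
  set.seed(11)
  for (i in 1:20) {
    p <- random_subject_params()
    gt <- build_skeleton(p)
    pp <- compute_posture(gt$skeleton)
    expect_lt(abs(pp$clavicle_asym_deg - p$clavicle_asym_deg), 1e-9)
    expect_lt(abs(pp$pelvic_oblique_deg - p$pelvic_oblique_deg), 1e-9)
    expect_lt(abs(pp$q_right_deg - p$q_right_deg), 1e-9)
    expect_lt(abs(pp$q_left_deg - p$q_left_deg), 1e-9)
    expect_lt(abs(pp$c7_csl_mm - p$c7_csl_mm), 1e-9)
    expect_lt(abs(pp$fhp_deg - p$fhp_deg), 1e-9)
  }
})

test_that("neutral pose is bilaterally symmetric", {
  gt <- build_skeleton(subject_params())
  s <- gt$skeleton
  pairs <- list(c("clavicle_highest_L", "clavicle_highest_R"),
                c("acromion_L", "acromion_R"),
                c("iliac_crest_mid_L", "iliac_crest_mid_R"),
                c("ASIS_L", "ASIS_R"), c("hip_L", "hip_R"),
                c("patella_center_L", "patella_center_R"),
                c("tibial_tuberosity_L", "tibial_tuberosity_R"),
                c("ankle_L", "ankle_R"), c("toe_L", "toe_R"),
                c("elbow_L", "elbow_R"), c("wrist_L", "wrist_R"))
  for (pr in pairs) {
    expect_equal(s[[pr[1]]]["x"], -s[[pr[2]]]["x"], tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_equal(s[[pr[1]]]["y"], s[[pr[2]]]["y"], tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("clavicle and head geometry match their closed forms", {
  gt <- build_skeleton(subject_params(clavicle_asym_deg = -2,
                                      shoulder_half_span = 180))
  dy <- gt$skeleton$clavicle_highest_L["y"] - gt$skeleton$clavicle_highest_R["y"]
  expect_equal(unname(dy), 360 * tan(2 * pi / 180), tolerance = 1e-9)
  expect_gt(dy, 0)  # negative angle = left raised

  # forward head: anterior ear offset over a 120 mm C7-to-ear rise
  p <- subject_params(stature = 120 / 0.071, fhp_deg = 7.9)
  gt <- build_skeleton(p)
  rise <- gt$skeleton$ear_canal["y"] - gt$skeleton$C7_center["y"]
  expect_equal(unname(rise), 120, tolerance = 1e-9)
  off <- gt$skeleton$ear_canal["z"] - gt$skeleton$C7_center["z"]
  expect_equal(unname(off), 120 * tan(7.9 * pi / 180), tolerance = 1e-9)
  expect_equal(unname(off), 16.65, tolerance = 1e-3)
})

test_that("infeasible limb configurations are rejected", {
  expect_error(build_skeleton(subject_params(q_right_deg = -8,
                                             q_left_deg = -7.9,
                                             pelvis_half_span = 60)),
               "infeasible posture")
})

test_that("rendering is deterministic with exact background depth", {
  gt <- pk_truth()
  cam <- pk_camera()
  s1 <- render_session(gt, cam, n_frames = 2, seed = 5)
  s2 <- render_session(gt, cam, n_frames = 2, seed = 5)
  for (v in c("front", "side", "back")) {
    expect_identical(s1$frames[[v]][[1]]$z, s2$frames[[v]][[1]]$z)
    expect_identical(s1$frames[[v]][[2]]$z, s2$frames[[v]][[2]]$z)
    # background pixels carry exactly the wall distance
    bgmask <- s1$truth$part_masks[[v]] == 0
    expect_true(all(s1$frames[[v]][[1]]$z[bgmask] ==
                      cam$background_distance))
    # body is always nearer than the wall
    expect_true(all(s1$frames[[v]][[1]]$z <= cam$background_distance))
  }
  # different noise per frame, same silhouette
  expect_false(identical(s1$frames$front[[1]]$z, s1$frames$front[[2]]$z))
})

test_that("rendered silhouette matches an independent ray-capsule oracle", {
  sess <- pk_clean_session()
  gt <- pk_env$clean_gt
  cam <- pk_camera()
  body <- sess$truth$part_masks$front > 0

  # independent oracle: min over the ray of the distance to each capsule
  # segment (convex in the ray parameter, so optimize() finds it)
  caps <- gt$capsules
  A <- subject_to_camera <- posturekit:::subject_to_camera
  Ac <- A(caps[, 1:3, drop = FALSE], "front", cam)
  Bc <- A(caps[, 4:6, drop = FALSE], "front", cam)
  seg_dist <- function(p, a, b) {
    ab <- b - a
    L2 <- sum(ab * ab)
    t <- if (L2 < 1e-9) 0 else min(max(sum((p - a) * ab) / L2, 0), 1)
    sqrt(sum((p - a - t * ab)^2))
  }
  ray_hits <- function(u, v) {
    d <- c((u - cam$cx) / cam$fx, (cam$cy - v) / cam$fy, 1)
    for (i in seq_len(nrow(caps))) {
      f <- function(t) seg_dist(t * d, Ac[i, ], Bc[i, ])
      if (optimize(f, c(500, 4000))$objective <= caps[i, 7]) return(TRUE)
    }
    FALSE
  }
  set.seed(3)
  us <- sample(0:639, 250, TRUE); vs <- sample(0:479, 250, TRUE)
  mismatch <- 0
  for (k in seq_along(us)) {
    u <- us[k]; v <- vs[k]
    # skip the 1 px boundary band
    nb <- body[max(1, v):min(480, v + 2), max(1, u):min(640, u + 2)]
    if (any(nb) && !all(nb)) next
    if (ray_hits(u, v) != body[v + 1, u + 1]) mismatch <- mismatch + 1
  }
  expect_equal(mismatch, 0)
})

test_that("clothing only moves clothed surfaces toward the camera", {
  p0 <- pk_params(noise_sd = 0, clothing_amplitude = 0)
  p1 <- pk_params(noise_sd = 0, clothing_amplitude = 15)
  cam <- pk_camera()
  s0 <- render_session(build_skeleton(p0), cam, n_frames = 1, seed = 4)
  s1 <- render_session(build_skeleton(p1), cam, n_frames = 1, seed = 4)
  d0 <- s0$frames$front[[1]]$z
  d1 <- s1$frames$front[[1]]$z
  expect_true(all(d1 <= d0 + 1))            # toward the camera only
  expect_true(all(d0 - d1 <= 15 + 1))       # bounded by the amplitude
  headmask <- s0$truth$part_masks$front == 1
  expect_true(all(d1[headmask] == d0[headmask]))  # head is never clothed
})

test_that("test-retest jitter behaves as specified", {
  p <- pk_params(posture_jitter_sd = 0)
  pr <- simulate_retest(p, pk_camera(), seed_a = 3, seed_b = 3, n_frames = 1)
  # zero jitter, equal seeds: bit-identical sessions
  expect_identical(pr$a$frames$front[[1]]$z, pr$b$frames$front[[1]]$z)
  expect_identical(unclass(pr$a$truth$params)[1:17],
                   unclass(pr$b$truth$params)[1:17])

  # jitter > 0: the difference SD matches the requested jitter (Monte Carlo)
  p <- pk_params(posture_jitter_sd = 0.7)
  d <- t(vapply(1:200, function(i) {
    pj <- jitter_subject(p, seed = i)
    c(pj$clavicle_asym_deg - p$clavicle_asym_deg,
      pj$fhp_deg - p$fhp_deg, pj$c7_csl_mm - p$c7_csl_mm)
  }, numeric(3)))
  for (j in 1:3) expect_lt(abs(sd(d[, j]) - 0.7) / 0.7, 0.15)
})

test_that("subjects wider than the field of view are rejected", {
  p <- subject_params(shoulder_half_span = 1500)
  expect_error(render_session(build_skeleton(p), pk_camera(), n_frames = 1,
                              seed = 1), "out of frame")
})
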