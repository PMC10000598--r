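#' Synthetic subject parameters
#'
#' Anthropometrics plus the six ground-truth posture parameters and the
#' capture noise model.  Defaults describe an average adult of the study
#' population standing 2.5 m from a consumer structured-light camera:
#' 5 mm depth noise, up to 15 mm of clothing offset, and a within-subject
#' re-standing jitter of 0.7 units per parameter between repeat captures.
#'
#' @param stature body height, mm.
#' @param shoulder_half_span half-distance between the acromial points, mm.
#' @param pelvis_half_span half-length of the pelvic (hip-to-hip) axis, mm.
#' @param upper_arm,forearm,thigh,shank segment lengths (axis extents), mm.
#' @param girth_scale unitless multiplier on all body radii.
#' @param clavicle_asym_deg,pelvic_oblique_deg,q_right_deg,q_left_deg,c7_csl_mm,fhp_deg
#'   the six ground-truth posture parameters (negative = left raised /
#'   tilted left; Q angles positive = valgus; FHP positive = head anterior).
#' @param clothing_amplitude maximum clothing offset toward the camera, mm.
#' @param noise_sd i.i.d. Gaussian depth noise on body pixels, mm.
#' @param posture_jitter_sd SD of the per-parameter perturbation between the
#'   two captures of a test-retest pair (each parameter's own unit).
#' @return object of class `subject_params`.
#' @export
subject_params <- function(stature = 1700, shoulder_half_span = 180,
                           pelvis_half_span = 95,
                           upper_arm = 300, forearm = 260,
                           thigh = 465, shank = 407,
                           girth_scale = 1,
                           clavicle_asym_deg = 0, pelvic_oblique_deg = 0,
                           q_right_deg = 0, q_left_deg = 0,
                           c7_csl_mm = 0, fhp_deg = 0,
                           clothing_amplitude = 15, noise_sd = 5,
                           posture_jitter_sd = 0.7) {
  p <- list(stature = stature, shoulder_half_span = shoulder_half_span,
            pelvis_half_span = pelvis_half_span, upper_arm = upper_arm,
            forearm = forearm, thigh = thigh, shank = shank,
            girth_scale = girth_scale,
            clavicle_asym_deg = clavicle_asym_deg,
            pelvic_oblique_deg = pelvic_oblique_deg,
            q_right_deg = q_right_deg, q_left_deg = q_left_deg,
            c7_csl_mm = c7_csl_mm, fhp_deg = fhp_deg,
            clothing_amplitude = clothing_amplitude, noise_sd = noise_sd,
            posture_jitter_sd = posture_jitter_sd)
  stopifnot(p$stature > 0, p$shoulder_half_span > 0, p$pelvis_half_span > 0,
            p$clothing_amplitude >= 0, p$noise_sd >= 0,
            p$posture_jitter_sd >= 0, p$girth_scale > 0)
  structure(p, class = "subject_params")
}

# Population used when sampling subjects: the study cohort's descriptive
# statistics (device degrees for angle parameters, reference mm for C7-CSL).
posture_population <- function() {
  list(mean = c(clavicle_asym_deg = -1.0, pelvic_oblique_deg = 0.7,
                q_right_deg = 0.9, q_left_deg = -3.1,
                c7_csl_mm = -3.0, fhp_deg = 7.9),
       sd = c(clavicle_asym_deg = 1.6, pelvic_oblique_deg = 1.6,
              q_right_deg = 7.9, q_left_deg = 4.0,
              c7_csl_mm = 13.3, fhp_deg = 6.3),
       lo = c(clavicle_asym_deg = -5.0, pelvic_oblique_deg = -2.6,
              q_right_deg = -8.0, q_left_deg = -7.9,
              c7_csl_mm = -59.0, fhp_deg = -5.0),
       hi = c(clavicle_asym_deg = 3.8, pelvic_oblique_deg = 6.4,
              q_right_deg = 14.0, q_left_deg = 13.5,
              c7_csl_mm = 36.0, fhp_deg = 29.0))
}

#' Draw a random subject from the study population
#'
#' Posture parameters are drawn from normal distributions with the cohort's
#' published means and SDs, truncated to the published ranges; stature and
#' girth vary mildly.  Draws that would make the limbs self-intersect are
#' rejected and redrawn.
#'
#' @param seed optional integer seed (uses the current RNG state if `NULL`).
#' @param ... overrides passed on to [subject_params()].
#' @return a `subject_params` object.
#' @export
random_subject_params <- function(seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  pop <- posture_population()
  for (try in 1:100) {
    vals <- rnorm(6, pop$mean, pop$sd)
    vals <- pmin(pmax(vals, pop$lo), pop$hi)
    names(vals) <- names(pop$mean)
    stature <- min(max(rnorm(1, 1634, 80), 1430), 1830)
    sc <- stature / 1700
    p <- subject_params(stature = stature,
                        shoulder_half_span = 180 * sc * runif(1, 0.95, 1.05),
                        pelvis_half_span = 95 * sc * runif(1, 0.95, 1.05),
                        upper_arm = 300 * sc, forearm = 260 * sc,
                        thigh = 465 * sc, shank = 407 * sc,
                        girth_scale = runif(1, 0.9, 1.1),
                        clavicle_asym_deg = vals[["clavicle_asym_deg"]],
                        pelvic_oblique_deg = vals[["pelvic_oblique_deg"]],
                        q_right_deg = vals[["q_right_deg"]],
                        q_left_deg = vals[["q_left_deg"]],
                        c7_csl_mm = vals[["c7_csl_mm"]],
                        fhp_deg = vals[["fhp_deg"]])
    p <- modifyList(p, list(...))
    class(p) <- "subject_params"
    gt <- tryCatch(build_skeleton(p), error = function(e) NULL)
    if (!is.null(gt)) return(p)
  }
  stop("could not draw a feasible subject")
}

body_radii <- function(params) {
  g <- params$girth_scale
  c(head = 85, neck = 55, torso_up = 110, torso_lo = 105, girdle = 55,
    pelvis = 85, thigh = 75, shank = 50, upper_arm = 45, forearm = 40,
    foot = 40) * g
}

#' Body part class names
#' @return the 12 part-class labels used by the segmentation stage.
#' @export
part_classes <- function() {
  c("head", "neck", "torso", "pelvis", "upper_arm_L", "upper_arm_R",
    "forearm_hand_L", "forearm_hand_R", "thigh_L", "thigh_R",
    "shank_foot_L", "shank_foot_R")
}

# anterior (+1) or posterior (-1) skin-surface z over the capsule union at
# coronal position (x, y); only capsules whose axis has constant z qualify
# (all but the feet).
surface_z <- function(x, y, capsules, side = 1) {
  best <- NA_real_
  for (i in seq_len(nrow(capsules))) {
    A <- capsules[i, 1:3]; B <- capsules[i, 4:6]; r <- capsules[i, 7]
    if (abs(A[3] - B[3]) > 1e-9) next
    ab <- B[1:2] - A[1:2]
    L2 <- sum(ab^2)
    t <- if (L2 < 1e-12) 0 else max(0, min(1, sum((c(x, y) - A[1:2]) * ab) / L2))
    d2 <- sum((c(x, y) - (A[1:2] + t * ab))^2)
    if (d2 < r^2) {
      z <- A[3] + side * sqrt(r^2 - d2)
      if (is.na(best) || side * z > side * best) best <- z
    }
  }
  if (is.na(best)) stop("surface query outside the body")
  best
}

# Solves the knee x position so that the recomputed signed Q angle equals
# the requested ground truth, with the ankle fixed under the hip.
solve_knee_x <- function(q_deg, side_sign, asis, ankle, yk, ykb, tendon) {
  qfun <- function(xk) {
    shank_dir <- c(ankle[1] - xk, ankle[2] - yk)
    alpha <- (yk - ykb) / (yk - ankle[2])
    px <- xk + alpha * (ankle[1] - xk)
    p <- c(px, ykb)
    u <- p - asis
    # tendon = patella - tib points up the shank axis; its extension through
    # the patella points down, i.e. along the knee-to-ankle direction
    w <- shank_dir
    side_sign * rad2deg(atan2(w[1] * u[2] - w[2] * u[1], sum(w * u))) - q_deg
  }
  lo <- asis[1] - 400; hi <- asis[1] + 400
  if (qfun(lo) * qfun(hi) > 0) stop("infeasible posture")
  r <- uniroot(qfun, c(lo, hi), tol = 1e-12)
  r$root
}

#' Build the ground-truth skeleton for a synthetic subject
#'
#' Places the 28 landmarks from the anthropometrics and deforms the pose so
#' that each of the six posture parameters, recomputed from the placed
#' points by [compute_posture()], equals the requested value to within
#' 1e-9.  Landmarks lie on the visible skin surface of the capsule-union
#' body so that a depth camera can observe them without bias.
#'
#' @param params a [subject_params()].
#' @return object of class `ground_truth` with fields `params`, `skeleton`
#'   (a [skeleton28()]), and `capsules` (the body model; one row per
#'   capsule: endpoints, radius, part class id).
#' @export
build_skeleton <- function(params) {
  p <- params
  h <- p$stature
  s <- h / 1700          # scale for small fixed offsets
  r <- body_radii(p)
  cls <- part_classes()
  cid <- function(nm) match(nm, cls)

  c7x <- p$c7_csl_mm
  c7y <- 0.865 * h
  eary <- 0.936 * h

  ## --- capsule axes (z = 0 coronal plane unless stated) -----------------
  caps <- list()
  add <- function(a, b, rad, part) {
    caps[[length(caps) + 1]] <<- c(a, b, rad, cid(part))
  }

  # trunk; the lower torso ends above the iliac crests so the pelvis is
  # frontally visible as one contiguous band (keeps its class region
  # convex in image coordinates, which the linear part classifier needs)
  add(c(0, 0.655 * h, 0), c(0, 0.70 * h, 0), r[["torso_lo"]], "torso")
  add(c(0, 0.70 * h, 0), c(c7x, 0.79 * h, 0), r[["torso_up"]], "torso")
  # shoulder girdle, tilted by the clavicle asymmetry
  yg <- c7y - r[["girdle"]]
  tc <- tan(deg2rad(p$clavicle_asym_deg))
  S <- p$shoulder_half_span
  acrR <- c(c7x + S, yg + S * tc, 0)
  acrL <- c(c7x - S, yg - S * tc, 0)
  add(acrL, acrR, r[["girdle"]], "torso")
  # neck (vertical) and head
  add(c(c7x, c7y, 0), c(c7x, c7y + 90 * s, 0), r[["neck"]], "neck")
  c7z <- -r[["neck"]]
  earz <- c7z + tan(deg2rad(p$fhp_deg)) * (eary - c7y)
  add(c(c7x, eary, earz), c(c7x, eary, earz), r[["head"]], "head")
  # pelvis, tilted by the pelvic obliquity
  yp <- 0.60 * h
  tp <- tan(deg2rad(p$pelvic_oblique_deg))
  P <- p$pelvis_half_span
  W <- P + r[["pelvis"]]
  pelvR <- c(P, yp + W * tp, 0)
  pelvL <- c(-P, yp - W * tp, 0)
  add(pelvL, pelvR, r[["pelvis"]], "pelvis")

  crest <- list(R = c(W, yp + W * tp, 0), L = c(-W, yp - W * tp, 0))
  asis <- list(R = c(0.5 * W, crest$R[2] - 40 * s, NA),
               L = c(-0.5 * W, crest$L[2] - 40 * s, NA))

  # legs: ankle fixed under the hip; knee solved to meet the Q angle
  yk <- 0.56 * h - p$thigh
  ya <- yk - p$shank
  ykb <- yk - (r[["thigh"]] - r[["shank"]])   # visible thigh/shank boundary
  ttl <- 80 * s                                # patella -> tibial tub drop
  if (ykb - ttl <= ya) stop("infeasible posture")
  leg <- list()
  for (sd_ in c("R", "L")) {
    sg <- if (sd_ == "R") 1 else -1
    q <- if (sd_ == "R") p$q_right_deg else p$q_left_deg
    ank <- c(sg * (P - 5 * s), ya)
    xk <- solve_knee_x(q, sg, asis[[sd_]][1:2], ank, yk, ykb, ttl)
    axis_x <- function(y) xk + (ank[1] - xk) * (yk - y) / (yk - ank[2])
    leg[[sd_]] <- list(hip = c(sg * P, 0.56 * h, 0), knee = c(xk, yk, 0),
                       ankle = c(ank, 0),
                       patella_xy = c(axis_x(ykb), ykb),
                       tib_xy = c(axis_x(ykb - ttl), ykb - ttl))
    add(leg[[sd_]]$hip, leg[[sd_]]$knee, r[["thigh"]],
        paste0("thigh_", sd_))
    add(leg[[sd_]]$knee, leg[[sd_]]$ankle, r[["shank"]],
        paste0("shank_foot_", sd_))
    add(c(ank[1], ya - 20 * s, 0), c(ank[1], 45 * s, 160 * s), r[["foot"]],
        paste0("shank_foot_", sd_))
  }
  # limb clearance: left and right shank surfaces must not intersect
  if (leg$R$patella_xy[1] - leg$L$patella_xy[1] < 2 * r[["shank"]] + 10)
    stop("infeasible posture")

  # arms, slightly abducted so the silhouette separates them from the trunk
  arm <- list()
  for (sd_ in c("R", "L")) {
    sg <- if (sd_ == "R") 1 else -1
    acr <- if (sd_ == "R") acrR else acrL
    elb <- acr + c(sg * sin(deg2rad(18)), -cos(deg2rad(18)), 0) * p$upper_arm
    wri <- elb + c(sg * sin(deg2rad(8)), -cos(deg2rad(8)), 0) * p$forearm
    arm[[sd_]] <- list(acr = acr, elbow = elb, wrist = wri)
    add(acr, elb, r[["upper_arm"]], paste0("upper_arm_", sd_))
    add(elb, wri, r[["forearm"]], paste0("forearm_hand_", sd_))
  }

  capsules <- do.call(rbind, caps)
  colnames(capsules) <- c("ax", "ay", "az", "bx", "by", "bz", "r", "part")

  zf <- function(pt) surface_z(pt[1], pt[2], capsules, 1)
  zb <- function(pt) surface_z(pt[1], pt[2], capsules, -1)

  # the "highest clavicle" pair sits at the shoulder half-span, so the
  # clavicle-asymmetry geometry is exactly y_R - y_L = 2 S tan(theta)
  xstar <- S
  pts <- list(
    vertex_head = c(c7x, eary + r[["head"]], earz),
    ear_canal = c(c7x, eary, earz),
    C7_center = c(c7x, c7y, zb(c(c7x, c7y))),
    sternum_center = c(c7x, 0.80 * h, zf(c(c7x, 0.80 * h))),
    clavicle_highest_L = c(c7x - xstar, yg - xstar * tc + r[["girdle"]], 0),
    clavicle_highest_R = c(c7x + xstar, yg + xstar * tc + r[["girdle"]], 0),
    acromion_L = c(c7x - (S + r[["girdle"]]), yg - (S + r[["girdle"]]) * tc, 0),
    acromion_R = c(c7x + (S + r[["girdle"]]), yg + (S + r[["girdle"]]) * tc, 0),
    elbow_L = c(arm$L$elbow[1:2], zf(arm$L$elbow)),
    elbow_R = c(arm$R$elbow[1:2], zf(arm$R$elbow)),
    wrist_L = c(arm$L$wrist[1:2], zf(arm$L$wrist)),
    wrist_R = c(arm$R$wrist[1:2], zf(arm$R$wrist)),
    T12_center = c(0, 0.66 * h, zb(c(0, 0.66 * h))),
    iliac_crest_mid_L = crest$L,
    iliac_crest_mid_R = crest$R,
    ASIS_L = c(asis$L[1:2], zf(asis$L)),
    ASIS_R = c(asis$R[1:2], zf(asis$R)),
    sacrum_center = c(0, yp, zb(c(0, yp))),
    hip_L = c(leg$L$hip[1:2], zf(leg$L$hip)),
    hip_R = c(leg$R$hip[1:2], zf(leg$R$hip)),
    patella_center_L = c(leg$L$patella_xy, zf(leg$L$patella_xy)),
    patella_center_R = c(leg$R$patella_xy, zf(leg$R$patella_xy)),
    tibial_tuberosity_L = c(leg$L$tib_xy, zf(leg$L$tib_xy)),
    tibial_tuberosity_R = c(leg$R$tib_xy, zf(leg$R$tib_xy)),
    ankle_L = c(leg$L$ankle[1:2], zf(leg$L$ankle)),
    ankle_R = c(leg$R$ankle[1:2], zf(leg$R$ankle)),
    toe_L = c(leg$L$ankle[1], 45 * s, 160 * s + r[["foot"]]),
    toe_R = c(leg$R$ankle[1], 45 * s, 160 * s + r[["foot"]]))

  structure(list(params = p, skeleton = skeleton28(pts),
                 capsules = capsules),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> stature %.0f mm, %d capsules\n",
              x$params$stature, nrow(x$capsules)))
  print(compute_posture(x$skeleton))
  invisible(x)
}

# evaluates the RNG-backed expression with a private seed, restoring the
# caller's RNG state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv())
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# smooth clothing field in [0, 1] over the image, seeded per session
clothing_field <- function(width, height, seed) {
  with_seed(seed * 7 + 3, {
    a <- runif(2, -1, 1); b <- runif(2, -1, 1)
    lam <- runif(2, 60, 140); phi <- runif(2, 0, 2 * pi)
    u <- matrix(seq_len(width) - 1, height, width, byrow = TRUE)
    v <- matrix(seq_len(height) - 1, height, width)
    f1 <- sin(2 * pi * (a[1] * u + b[1] * v) / lam[1] + phi[1])
    f2 <- sin(2 * pi * (a[2] * u + b[2] * v) / lam[2] + phi[2])
    (1 + f1 * f2) / 2
  })
}

#' Render a synthetic capture session
#'
#' Z-buffers the capsule-union body against the background wall for each
#' view, overlays a smooth seeded clothing offset (surface moved toward the
#' camera over torso and limbs, never the head or neck), and adds i.i.d.
#' Gaussian depth noise per frame.  The ground truth (including per-view
#' per-pixel part masks) is attached to the returned session as `$truth`.
#'
#' @param gt a [build_skeleton()] result.
#' @param camera a [camera_model()].
#' @param n_frames frames per view (default 20, i.e. 2-3 s at ~8 fps).
#' @param seed integer seed; identical seeds give bit-identical sessions.
#' @return a [capture_session()] with a `truth` field.
#' @export
render_session <- function(gt, camera, n_frames = 20, seed = 1) {
  stopifnot(n_frames >= 1)
  width <- round(2 * camera$cx); height <- round(2 * camera$cy)
  cls <- part_classes()
  clothed <- cid_set <- match(c("torso", "pelvis", "upper_arm_L",
                                "upper_arm_R", "forearm_hand_L",
                                "forearm_hand_R", "thigh_L", "thigh_R",
                                "shank_foot_L", "shank_foot_R"), cls)
  cloth <- clothing_field(width, height, seed) * gt$params$clothing_amplitude

  frames <- list(); masks <- list(); background <- list()
  bg <- matrix(as.integer(round(camera$background_distance)), height, width)
  with_seed(seed, {
    for (view in c("front", "side", "back")) {
      caps <- gt$capsules
      A <- subject_to_camera(caps[, 1:3, drop = FALSE], view, camera)
      B <- subject_to_camera(caps[, 4:6, drop = FALSE], view, camera)
      cc <- cbind(A, B, caps[, 7], caps[, 8])
      rend <- .render_capsules(cc, width, height, camera$fx, camera$fy,
                               camera$cx, camera$cy,
                               camera$background_distance)
      body <- rend$part > 0L
      if (any(body[1, ]) || any(body[height, ]) || any(body[, 1]) ||
          any(body[, width]))
        stop("subject out of frame")
      depth0 <- rend$depth
      dressed <- body & matrix(rend$part %in% clothed, height, width)
      depth0[dressed] <- depth0[dressed] - cloth[dressed]
      masks[[view]] <- rend$part
      nb <- sum(body)
      frames[[view]] <- lapply(seq_len(n_frames), function(i) {
        z <- depth0
        if (gt$params$noise_sd > 0)
          z[body] <- z[body] + rnorm(nb, 0, gt$params$noise_sd)
        z <- pmin(pmax(round(z), 1), 65535)
        z[!body] <- as.integer(round(camera$background_distance))
        depth_frame(z, view = view, frame_index = i - 1L)
      })
      background[[view]] <- depth_frame(bg, view = view, frame_index = -1L)
    }
  })
  session <- capture_session(frames, background, camera)
  gt$part_masks <- masks
  session$truth <- gt
  session
}

#' Perturb a subject's posture for a repeat capture
#'
#' Adds `N(0, posture_jitter_sd^2)` to each of the six posture parameters
#' (re-drawn, up to 50 times, if the perturbed pose is infeasible).
#'
#' @param params a [subject_params()].
#' @param seed integer seed.
#' @return a `subject_params` object.
#' @export
jitter_subject <- function(params, seed) {
  if (params$posture_jitter_sd == 0) return(params)
  with_seed(seed * 11 + 5, {
    for (try in 1:50) {
      cand <- params
      for (nm in c("clavicle_asym_deg", "pelvic_oblique_deg", "q_right_deg",
                   "q_left_deg", "c7_csl_mm", "fhp_deg"))
        cand[[nm]] <- params[[nm]] + rnorm(1, 0, params$posture_jitter_sd)
      ok <- tryCatch({ build_skeleton(cand); TRUE },
                     error = function(e) FALSE)
      if (ok) break
    }
    cand
  })
}

#' Simulate a test-retest capture pair
#'
#' Two sessions of the same subject taken minutes apart: the second
#' re-samples clothing and noise, and perturbs each posture parameter by
#' `N(0, posture_jitter_sd^2)` to model imperfect re-standing.
#'
#' @param params a [subject_params()].
#' @param camera a [camera_model()].
#' @param seed_a,seed_b seeds for the two captures.
#' @param n_frames frames per view.
#' @return `list(a = session, b = session)`; each session carries its own
#'   ground truth in `$truth`.
#' @export
simulate_retest <- function(params, camera = camera_model(),
                            seed_a = 1, seed_b = 2, n_frames = 20) {
  gt_a <- build_skeleton(params)
  gt_b <- build_skeleton(jitter_subject(params, seed_b))
  list(a = render_session(gt_a, camera, n_frames, seed_a),
       b = render_session(gt_b, camera, n_frames, seed_b))
}
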