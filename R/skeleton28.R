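#' The 28-point skeleton
#'
#' @param points named list of 28 `c(x, y, z)` subject-frame points (mm).
#' @return object of class `skeleton28`.
#' @export
skeleton28 <- function(points) {
  nms <- skeleton28_names()
  miss <- setdiff(nms, names(points))
  if (length(miss)) stop("skeleton28 requires 28 points; missing: ",
                         paste(miss, collapse = ", "))
  points <- points[nms]
  ok <- vapply(points, function(p) length(p) == 3 && all(is.finite(p)),
               logical(1))
  if (!all(ok)) stop("non-finite landmark: ",
                     paste(nms[!ok], collapse = ", "))
  points <- lapply(points, function(p) { names(p) <- c("x", "y", "z"); p })
  structure(points, class = "skeleton28")
}

#' Landmark names of the 28-point skeleton
#' @return character vector of length 28.
#' @export
skeleton28_names <- function() {
  c("vertex_head", "ear_canal", "C7_center", "sternum_center",
    "clavicle_highest_L", "clavicle_highest_R", "acromion_L", "acromion_R",
    "elbow_L", "elbow_R", "wrist_L", "wrist_R", "T12_center",
    "iliac_crest_mid_L", "iliac_crest_mid_R", "ASIS_L", "ASIS_R",
    "sacrum_center", "hip_L", "hip_R", "patella_center_L",
    "patella_center_R", "tibial_tuberosity_L", "tibial_tuberosity_R",
    "ankle_L", "ankle_R", "toe_L", "toe_R")
}

#' @export
print.skeleton28 <- function(x, ...) {
  cat("<skeleton28>\n")
  m <- do.call(rbind, unclass(x))
  print(round(m, 1))
  invisible(x)
}

#' @export
as.data.frame.skeleton28 <- function(x, ...) {
  m <- do.call(rbind, unclass(x))
  data.frame(landmark = rownames(m), x = m[, 1], y = m[, 2], z = m[, 3],
             row.names = NULL)
}

#' Export a skeleton as JSON
#' @param skeleton a [skeleton28()].
#' @param path output path.
#' @export
write_skeleton_json <- function(skeleton, path) {
  writeLines(jsonlite::toJSON(lapply(unclass(skeleton), unname),
                              digits = NA), path)
  invisible(path)
}

#' Least-squares quadratic fit to a depth point cloud
#'
#' Fits `z = a x^2 + b x + c` by least squares.  The vertex `x* = -b/(2a)`
#' is reported only when the curvature is meaningful (`|a| > 1e-6` per mm);
#' otherwise the fit is flagged flat.
#'
#' @param x,z coordinate vectors (mm); at least 3 points with 3 distinct
#'   x values.
#' @return object of class `quadratic_fit`: `a`, `b`, `c`, `rmse`, `vertex`
#'   (`NA` when flat), `flat`.
#' @export
fit_quadratic <- function(x, z) {
  keep <- is.finite(x) & is.finite(z)
  x <- x[keep]; z <- z[keep]
  if (length(x) < 3 || length(unique(x)) < 3) stop("underdetermined fit")
  m <- mean(x)
  t <- x - m
  co <- unname(qr.solve(cbind(1, t, t^2), z))
  a <- co[3]; b <- co[2] - 2 * co[3] * m
  cc <- co[1] - co[2] * m + co[3] * m^2
  resid <- z - (a * x^2 + b * x + cc)
  flat <- abs(a) <= 1e-6
  structure(list(a = a, b = b, c = cc, rmse = sqrt(mean(resid^2)),
                 vertex = if (flat) NA_real_ else -b / (2 * a), flat = flat),
            class = "quadratic_fit")
}

#' @export
print.quadratic_fit <- function(x, ...) {
  cat(sprintf("<quadratic_fit> z = %.4g x^2 + %.4g x + %.4g (rmse %.2f%s)\n",
              x$a, x$b, x$c, x$rmse,
              if (x$flat) ", flat" else sprintf(", vertex %.2f", x$vertex)))
  invisible(x)
}

qeval <- function(fit, x) fit$a * x^2 + fit$b * x + fit$c

#' Landmark definition registry
#'
#' One definition per skeleton point: the source view, the part class whose
#' pixels are scanned, the scan band (fractions of the part region), the
#' fit plane and extremum rule, and dependencies on previously located
#' points.  The registry is this package's own: landmark sets of this kind
#' are device-internal, so the choices are documented here and in the
#' methods vignette.
#'
#' @return named list of landmark definitions (class `landmark_registry`).
#' @export
landmark_registry <- function() {
  def <- function(name, view, part, strategy, side = 0, band = c(0, 1),
                  eval_at = NULL, plane = "xy", extremum = "midline",
                  depends = character()) {
    list(name = name, view = view, part = part, strategy = strategy,
         side = side, band = band, eval_at = eval_at, plane = plane,
         extremum = extremum, depends = depends)
  }
  defs <- list(
    def("vertex_head", "front", "head", "contour_top", band = c(-0.6, 0.6),
        extremum = "vertex"),
    def("ear_canal", "side", "head", "ear", extremum = "midline",
        plane = "zy"),
    def("C7_center", "back", "neck", "c7", band = c(0.45, 0.85),
        extremum = "midline"),
    def("T12_center", "back", "torso", "axis", band = c(0.3, 0.75),
        eval_at = "frac_top:0.67"),
    def("sternum_center", "front", "torso", "axis", band = c(0.25, 0.6),
        eval_at = "frac_top:0.21"),
    def("clavicle_highest_L", "front", "torso", "shoulder", side = -1,
        band = c(0.45, 0.85), eval_at = 0.766, plane = "xz"),
    def("clavicle_highest_R", "front", "torso", "shoulder", side = 1,
        band = c(0.45, 0.85), eval_at = 0.766, plane = "xz"),
    def("acromion_L", "front", "torso", "shoulder", side = -1,
        band = c(0.70, 0.98), eval_at = 0.95),
    def("acromion_R", "front", "torso", "shoulder", side = 1,
        band = c(0.70, 0.98), eval_at = 0.95),
    def("iliac_crest_mid_L", "front", "pelvis", "edge_profile", side = -1,
        band = c(0.1, 0.9), extremum = "vertex", plane = "xz"),
    def("iliac_crest_mid_R", "front", "pelvis", "edge_profile", side = 1,
        band = c(0.1, 0.9), extremum = "vertex", plane = "xz"),
    def("sacrum_center", "back", "pelvis", "axis", band = c(0.25, 0.75),
        eval_at = "crest_mean",
        depends = c("iliac_crest_mid_L", "iliac_crest_mid_R")),
    def("ASIS_L", "front", "pelvis", "asis", side = -1,
        depends = c("iliac_crest_mid_L", "iliac_crest_mid_R")),
    def("ASIS_R", "front", "pelvis", "asis", side = 1,
        depends = c("iliac_crest_mid_L", "iliac_crest_mid_R")),
    def("hip_L", "front", "thigh_L", "axis", side = -1, band = c(0.05, 0.5),
        eval_at = "top"),
    def("hip_R", "front", "thigh_R", "axis", side = 1, band = c(0.05, 0.5),
        eval_at = "top"),
    def("patella_center_L", "front", "shank_foot_L", "axis", side = -1,
        band = c(0.3, 0.95), eval_at = "score_boundary"),
    def("patella_center_R", "front", "shank_foot_R", "axis", side = 1,
        band = c(0.3, 0.95), eval_at = "score_boundary"),

    def("tibial_tuberosity_L", "front", "shank_foot_L", "axis", side = -1,
        band = c(0.3, 0.95), eval_at = "below_patella:80",
        depends = "patella_center_L"),
    def("tibial_tuberosity_R", "front", "shank_foot_R", "axis", side = 1,
        band = c(0.3, 0.95), eval_at = "below_patella:80",
        depends = "patella_center_R"),
    def("ankle_L", "front", "shank_foot_L", "axis", side = -1,
        band = c(0.3, 0.95), eval_at = "above_bottom:75"),
    def("ankle_R", "front", "shank_foot_R", "axis", side = 1,
        band = c(0.3, 0.95), eval_at = "above_bottom:75"),
    def("toe_L", "front", "shank_foot_L", "toe", side = -1),
    def("toe_R", "front", "shank_foot_R", "toe", side = 1),
    def("elbow_L", "front", "upper_arm_L", "axis", side = -1,
        band = c(0.1, 0.9), eval_at = "bottom"),
    def("elbow_R", "front", "upper_arm_R", "axis", side = 1,
        band = c(0.1, 0.9), eval_at = "bottom"),
    def("wrist_L", "front", "forearm_hand_L", "axis", side = -1,
        band = c(0.1, 0.75), eval_at = "above_bottom_halfwidth"),
    def("wrist_R", "front", "forearm_hand_R", "axis", side = 1,
        band = c(0.1, 0.75), eval_at = "above_bottom_halfwidth"))
  names(defs) <- vapply(defs, `[[`, "", "name")
  stopifnot(length(defs) == 28)
  structure(defs, class = "landmark_registry")
}

# ---- per-view pixel context ------------------------------------------------

# Back-projects every silhouette pixel and attaches the predicted part
# class and a per-part clothing estimate (95th percentile of the
# per-superpixel residual against a smooth quadratic depth trend, capped).
view_context <- function(frame, mask, spmap, labeling, camera,
                         clothing_cap = 25) {
  idx <- which(mask$mask)
  # filled interior holes (depth dropout, enclosed gaps between limbs)
  # carry no usable geometry: keep them out of the landmark scans
  idx <- idx[frame$z[idx] > 0 &
               frame$z[idx] < camera$background_distance - 100]
  v <- (idx - 1) %% nrow(mask$mask)
  u <- (idx - 1) %/% nrow(mask$mask)
  Zc <- as.numeric(frame$z[idx])
  world <- pixel_to_world_z(camera, u, v, Zc, frame$view)
  cls <- labeling$class[spmap$labels[idx] + 1L]

  # clothing estimate per part from superpixel-mean depths; the percentile
  # is taken over the central band of the part only, where the limb's own
  # curvature is well captured by the quadratic trend and does not inflate
  # the residuals
  ctr <- spmap$centers
  spcls <- labeling$class
  est <- stats::setNames(rep(0, length(unique(spcls))), unique(spcls))
  for (p in names(est)) {
    jj <- which(spcls == p)
    if (length(jj) >= 8) {
      cu <- ctr[jj, "col"]; cv <- ctr[jj, "row"]; cz <- ctr[jj, "depth"]
      X <- cbind(1, cu, cv, cu^2, cv^2, cu * cv)
      fitz <- tryCatch(X %*% qr.solve(X, cz), error = function(e) cz)
      uc <- median(cu)
      uh <- max((quantile(cu, 0.98) - quantile(cu, 0.02)) / 2, 1)
      vc <- median(cv)
      vh <- max((quantile(cv, 0.98) - quantile(cv, 0.02)) / 2, 1)
      central <- abs(cu - uc) <= 0.6 * uh & abs(cv - vc) <= 0.55 * vh
      if (sum(central) >= 5)
        est[p] <- min(max(quantile((fitz - cz)[central], 0.95), 0),
                      clothing_cap)
      else
        est[p] <- min(max(quantile(fitz - cz, 0.95), 0), clothing_cap)
    }
  }
  spw <- pixel_to_world_z(camera, ctr[, "col"], ctr[, "row"],
                          ctr[, "depth"], frame$view)
  # topmost pixel per image column (used by every shoulder-contour scan)
  o <- order(u, world[, 2])
  top_idx <- o[!duplicated(u[o], fromLast = TRUE)]
  list(view = frame$view, u = u, v = v, Zc = Zc, top_idx = top_idx,
       x = world[, 1], y = world[, 2], z = world[, 3],
       cls = cls, camera = camera, clothing = est,
       sp_x = spw[, 1], sp_y = spw[, 2], sp_class = spcls,
       sp_scores = labeling$scores, sp_classes = colnames(labeling$scores))
}

# pixels of one predicted part class, with stray misclassified superpixels
# trimmed away (anything far outside the class's median absolute spread)
part_sel <- function(ctx, part) {
  sel <- which(ctx$cls == part)
  if (length(sel) < 5) return(sel)
  mx <- median(ctx$x[sel]); my <- median(ctx$y[sel])
  dx <- max(4 * mad(ctx$x[sel]), 80)
  dy <- max(4 * mad(ctx$y[sel]), 80)
  sel[abs(ctx$x[sel] - mx) <= dx & abs(ctx$y[sel] - my) <= dy]
}

# corrected world point of pixel i: measured depth pushed toward the bone
# surface by the part's clothing estimate
ctx_point <- function(ctx, i) {
  est <- ctx$clothing[ctx$cls[i]]
  est[is.na(est)] <- 0
  p <- pixel_to_world_z(ctx$camera, ctx$u[i], ctx$v[i], ctx$Zc[i] + est,
                        ctx$view)
  p
}

ctx_z_near <- function(ctx, x0, y0, cls = NULL) {
  sel <- if (is.null(cls)) seq_along(ctx$x) else which(ctx$cls %in% cls)
  if (!length(sel)) sel <- seq_along(ctx$x)
  i <- sel[which.min((ctx$x[sel] - x0)^2 + (ctx$y[sel] - y0)^2)]
  ctx_point(ctx, i)[, 3]
}

# depth coordinate at a tangential silhouette edge: on a quadric surface
# z^2 is quadratic in the in-plane offsets from the edge point, so the
# intercept of z^2 regressed on (d, d^2, dy^2) estimates z at the edge
# itself without the knife-edge bias of reading a grazing pixel.
edge_z <- function(delta, dy, z, est) {
  z <- z + ifelse(z >= 0, -est, est)   # clothing acts along the view axis
  keep <- delta >= 0 & delta <= 35
  if (sum(keep) < 8) return(if (any(delta < 5)) median(z[delta < 5]) else 0)
  co <- tryCatch(
    qr.solve(cbind(1, delta[keep], delta[keep]^2, dy[keep]^2), z[keep]^2),
    error = function(e) c(median(z[keep])^2, 0, 0, 0))
  sign(median(z[keep])) * sqrt(max(co[1], 0))
}

# ---- landmark strategies ---------------------------------------------------

# Full-silhouette top contour of the shoulder region: per image column the
# topmost silhouette pixel, referenced to the head-centroid midline.  Being
# classifier-free, this is the most stable structure in the upper body.
# Returns the midline, the shoulder half-width (where the contour falls off
# past the acromion) and the contour points of one side band.
shoulder_scan <- function(ctx, shat, side, band) {
  hsel <- part_sel(ctx, "head")
  xmid <- if (length(hsel) >= 10) median(ctx$x[hsel]) else median(ctx$x)
  # the topmost pixel center sits below the surface apex by half a pixel
  # on average; correct by half the pixel pitch at the measured depth
  j <- ctx$top_idx
  pts <- cbind(ctx$x[j], ctx$y[j] + 0.5 * ctx$Zc[j] / ctx$camera$fy, j)
  dd <- side * (pts[, 1] - xmid)
  lev0 <- pts[dd >= 105 * shat & dd <= 165 * shat, 2]
  if (length(lev0) < 3) stop("shoulder contour not visible")
  lev0 <- lev0[abs(lev0 - median(lev0)) <= 50]   # drop head-sliver spikes
  level <- median(lev0)
  beyond <- which(dd > 165 * shat & pts[, 2] < level - 60)
  W <- if (length(beyond)) min(dd[beyond]) else max(dd)
  inb <- which(dd / W >= band[1] & dd / W <= band[2] &
                 abs(pts[, 2] - level) <= 60)
  if (length(inb) < 6) stop("shoulder contour not visible")
  list(xmid = xmid, W = W, pts = pts[inb, , drop = FALSE], level = level)
}

# clavicle-highest / acromion: quadratic fit to the shoulder contour,
# evaluated at a fixed fraction of the shoulder half-width
loc_shoulder <- function(def, ctx, shat) {
  sc <- shoulder_scan(ctx, shat, def$side, def$band)
  fit <- fit_quadratic(sc$pts[, 1], sc$pts[, 2])
  xstar <- sc$xmid + def$side * def$eval_at * sc$W
  ystar <- qeval(fit, xstar)
  nearby <- which(abs(ctx$x - xstar) <= 20 & ctx$y <= ystar + 5 &
                    ctx$y >= ystar - 35)
  est <- ctx$clothing["torso"]; est[is.na(est)] <- 0
  zstar <- if (def$plane == "xz" && length(nearby) >= 6)
    edge_z(ystar - ctx$y[nearby], ctx$x[nearby] - xstar, ctx$z[nearby], est)
  else ctx_z_near(ctx, xstar, ystar)
  list(point = c(xstar, ystar, zstar), rmse = fit$rmse)
}

# C7: midline x from the head centroid, height from the shoulder contour
# of both sides extrapolated to the midline, depth from the neck pixels
# just above the shoulder line
loc_c7 <- function(def, ctx, shat) {
  scL <- shoulder_scan(ctx, shat, -1, c(0.45, 0.85))
  scR <- shoulder_scan(ctx, shat, 1, c(0.45, 0.85))
  pts <- rbind(scL$pts, scR$pts)
  fit <- fit_quadratic(pts[, 1], pts[, 2])
  xstar <- scR$xmid
  ystar <- qeval(fit, xstar)
  nsel <- part_sel(ctx, "neck")
  nsel <- nsel[ctx$y[nsel] >= ystar - 10 & ctx$y[nsel] <= ystar + 45 * shat &
                 abs(ctx$x[nsel] - xstar) <= 18]
  zstar <- if (length(nsel) >= 8) median(ctx$z[nsel])
  else ctx_z_near(ctx, xstar, ystar + 20, cls = "neck")
  list(point = c(xstar, ystar, zstar), rmse = fit$rmse)
}

loc_contour_top <- function(def, ctx, shat) {
  sel <- part_sel(ctx, def$part)
  if (!length(sel)) stop("landmark unlocatable: ", def$name)
  x <- ctx$x[sel]; y <- ctx$y[sel]
  ytop <- max(y); ybot <- min(y)
  topband <- sel[y >= ytop - 0.35 * (ytop - ybot)]
  xs <- ctx$x[topband]
  xmid <- (quantile(xs, 0.005) + quantile(xs, 0.995)) / 2
  W <- (quantile(xs, 0.995) - quantile(xs, 0.005)) / 2
  if (def$side == 0) {
    inband <- sel[abs(x - xmid) <= def$band[2] * W]
  } else {
    rel <- def$side * (x - xmid) / W
    inband <- sel[rel >= def$band[1] & rel <= def$band[2]]
  }
  if (length(inband) < 10) stop("landmark unlocatable: ", def$name)
  colv <- ctx$u[inband]
  top <- tapply(seq_along(inband), colv, function(jj) {
    j <- inband[jj][which.max(ctx$y[inband[jj]])]
    c(ctx$x[j], ctx$y[j] + 0.5 * ctx$Zc[j] / ctx$camera$fy)
  })
  pts <- do.call(rbind, top)
  fit <- fit_quadratic(pts[, 1], pts[, 2])
  if (def$extremum == "vertex" && !fit$flat &&
      fit$vertex > min(pts[, 1]) && fit$vertex < max(pts[, 1])) {
    xstar <- fit$vertex
  } else if (def$extremum == "vertex") {
    xstar <- unname(xmid)
  } else {
    xstar <- unname(xmid + def$side * def$eval_at * W)
  }
  ystar <- qeval(fit, xstar)
  nearby <- sel[abs(x - xstar) <= 20 & y <= ystar + 5 & y >= ystar - 35]
  est <- ctx$clothing[def$part]; est[is.na(est)] <- 0
  zstar <- if (def$plane == "xz" && length(nearby) >= 6)
    edge_z(ystar - ctx$y[nearby], ctx$z[nearby], est)
  else ctx_z_near(ctx, xstar, ystar)
  list(point = c(xstar, ystar, zstar), rmse = fit$rmse)
}

loc_edge_profile <- function(def, ctx, shat) {
  sel <- part_sel(ctx, def$part)
  if (!length(sel)) stop("landmark unlocatable: ", def$name)
  sg <- def$side
  xmid <- median(ctx$x[sel])
  sside <- sel[sg * (ctx$x[sel] - xmid) > 0]
  if (length(sside) < 20) stop("landmark unlocatable: ", def$name)
  rows <- ctx$v[sside]
  edge <- tapply(seq_along(sside), rows, function(jj) {
    j <- sside[jj][which.max(sg * ctx$x[sside[jj]])]
    c(ctx$x[j] + sg * 0.5 * ctx$Zc[j] / ctx$camera$fx, ctx$y[j])
  })
  pts <- do.call(rbind, edge)
  ylo <- quantile(pts[, 2], def$band[1]); yhi <- quantile(pts[, 2], def$band[2])
  inb <- pts[, 2] >= ylo & pts[, 2] <= yhi
  if (sum(inb) < 5) inb <- rep(TRUE, nrow(pts))
  y0 <- pts[inb, 2][which.max(sg * pts[inb, 1])]
  # fit only the top of the edge bump: the lower flank is often clipped by
  # the neighbouring part class, which would bias a fixed window
  emax <- max(sg * pts[inb, 1])
  fine <- inb & sg * pts[, 1] > emax - 25 & abs(pts[, 2] - y0) <= 60
  if (sum(fine) < 4) fine <- inb & abs(pts[, 2] - y0) <= 35
  if (sum(fine) < 4) fine <- inb
  fit <- fit_quadratic(pts[fine, 2], sg * pts[fine, 1])
  ystar <- if (!fit$flat && fit$vertex > min(pts[fine, 2]) - 10 &&
               fit$vertex < max(pts[fine, 2]) + 10) fit$vertex else y0
  xstar <- sg * qeval(fit, ystar)
  nearby <- sel[abs(ctx$y[sel] - ystar) <= 20 &
                  sg * (xstar - ctx$x[sel]) >= 0 &
                  sg * (xstar - ctx$x[sel]) <= 35]
  est <- ctx$clothing[def$part]; est[is.na(est)] <- 0
  zstar <- if (length(nearby) >= 6)
    edge_z(sg * (xstar - ctx$x[nearby]), ctx$y[nearby] - ystar,
           ctx$z[nearby], est)
  else ctx_z_near(ctx, xstar, ystar)
  list(point = c(xstar, ystar, zstar), rmse = fit$rmse)
}

loc_axis <- function(def, ctx, shat, located) {
  sel <- part_sel(ctx, def$part)
  if (length(sel) < 15) stop("landmark unlocatable: ", def$name)
  ytop <- max(ctx$y[sel]); ybot <- min(ctx$y[sel]); H <- ytop - ybot
  # band measured from the top of the part region
  blo <- ytop - def$band[2] * H
  bhi <- ytop - def$band[1] * H
  inb <- sel[ctx$y[sel] >= blo & ctx$y[sel] <= bhi]
  if (length(inb) < 15) inb <- sel
  rows <- ctx$v[inb]
  if (def$side != 0) {
    # lateral limbs: anchor each row at the lateral silhouette edge and
    # keep one limb-width of pixels, so medially misclassified pixels of
    # the adjacent limb cannot drag the axis (legs may touch at the knees)
    nrow_px <- tapply(seq_along(inb), rows, length)
    halfw <- tapply(seq_along(inb), rows, function(jj)
      (max(ctx$x[inb[jj]]) - min(ctx$x[inb[jj]])) / 2)
    rhat <- max(median(halfw[nrow_px >= 5]), 18)
    ax <- tapply(seq_along(inb), rows, function(jj) {
      if (length(jj) < 5) return(c(NA_real_, NA_real_))
      xr <- ctx$x[inb[jj]]
      lat <- if (def$side > 0) max(xr) else min(xr)
      own <- abs(xr - lat) <= 2.2 * rhat
      c(mean(xr[own]), mean(ctx$y[inb[jj]][own]))
    })
  } else {
    ax <- tapply(seq_along(inb), rows, function(jj)
      c(mean(ctx$x[inb[jj]]), mean(ctx$y[inb[jj]])))
  }
  pts <- do.call(rbind, ax)
  pts <- pts[is.finite(pts[, 1]), , drop = FALSE]
  if (nrow(pts) < 3) stop("landmark unlocatable: ", def$name)
  # reject rows whose mean is pulled far off the axis trend by
  # misclassified superpixels
  dev <- abs(pts[, 1] - median(pts[, 1]))
  keep <- dev <= max(4 * mad(pts[, 1]), 25)
  if (sum(keep) >= 3) pts <- pts[keep, , drop = FALSE]
  # limb and trunk axes are straight: a line is the right model, and it
  # extrapolates stably to the joint at the end of the part region (a
  # quadratic would amplify row noise there and tilt short joint vectors)
  co <- qr.solve(cbind(1, pts[, 2]), pts[, 1])
  fit <- list(a = 0, b = co[2], c = co[1],
              rmse = sqrt(mean((pts[, 1] - co[1] - co[2] * pts[, 2])^2)),
              flat = TRUE)
  ev <- def$eval_at
  ystar <- if (identical(ev, "score_boundary")) {
    # sub-superpixel joint location: the thigh-vs-shank score margin of the
    # superpixels along the limb crosses zero at the class boundary, which
    # is far finer than the ~one-superpixel quantization of the bbox top
    axis_x0 <- function(y) fit$c + fit$b * y
    thigh_part <- sub("shank_foot", "thigh", def$part)
    jt <- match(thigh_part, def_classes <- ctx$sp_classes)
    js <- match(def$part, def_classes)
    cand <- which(ctx$sp_class %in% c(def$part, thigh_part) &
                    abs(ctx$sp_x - axis_x0(ctx$sp_y)) <= 60 &
                    abs(ctx$sp_y - ytop) <= 100)
    ystar <- ytop
    if (length(cand) >= 4 && !is.na(jt) && !is.na(js)) {
      dmarg <- ctx$sp_scores[cand, jt] - ctx$sp_scores[cand, js]
      co <- tryCatch(unname(qr.solve(cbind(1, ctx$sp_y[cand]), dmarg)),
                     error = function(e) c(0, 0))
      if (abs(co[2]) > 1e-8) {
        root <- -co[1] / co[2]
        if (abs(root - ytop) <= 60) {
          # the visible thigh/shank transition is where the thigh sphere
          # loses the depth buffer, sqrt(r_t^2 - r_s^2) below the joint;
          # the joint itself sits r_t - r_s below the knee center.  With
          # the canonical 75/50 mm radii the class boundary is therefore
          # sqrt(75^2-50^2) - 25 ~ 31 mm (times girth) below the patella.
          ghat <- min(max(rhat / 50, 0.8), 1.2)
          ystar <- root + 30.9 * ghat
        }
      }
    }
    ystar
  } else if (identical(ev, "top")) ytop
  else if (identical(ev, "bottom")) ybot
  else if (identical(ev, "center")) (ytop + ybot) / 2
  else if (startsWith(ev, "frac_top:"))
    ytop - as.numeric(sub("frac_top:", "", ev)) * H
  else if (startsWith(ev, "below_patella:")) {
    dep <- located[[def$depends[1]]]
    if (is.null(dep)) stop("landmark unlocatable: ", def$name)
    dep$point[2] - as.numeric(sub("below_patella:", "", ev)) * shat
  } else if (identical(ev, "crest_mean")) {
    cl <- located[["iliac_crest_mid_L"]]; cr <- located[["iliac_crest_mid_R"]]
    if (is.null(cl) || is.null(cr)) (ytop + ybot) / 2
    else (cl$point[2] + cr$point[2]) / 2
  } else if (startsWith(ev, "above_bottom:"))
    ybot + as.numeric(sub("above_bottom:", "", ev)) * shat
  else if (identical(ev, "above_bottom_halfwidth")) {
    hw <- tapply(seq_along(inb), rows, function(jj)
      (max(ctx$x[inb[jj]]) - min(ctx$x[inb[jj]])) / 2)
    ybot + median(hw)
  } else stop("unknown eval rule ", ev)
  xstar <- qeval(fit, ystar)
  zrule <- if (def$name == "C7_center") "band_median" else "near"
  zstar <- if (zrule == "band_median") {
    near <- sel[ctx$y[sel] <= ybot + 25]
    est <- ctx$clothing[def$part]; est[is.na(est)] <- 0
    median(ctx$z[near]) + (if (ctx$view == "back") est else -est)
  } else ctx_z_near(ctx, xstar, ystar)
  list(point = c(xstar, ystar, zstar), rmse = fit$rmse, fit = fit,
       ytop = ytop, ybot = ybot)
}

loc_toe <- function(def, ctx, shat) {
  sel <- part_sel(ctx, def$part)
  if (!length(sel)) stop("landmark unlocatable: ", def$name)
  ybot <- min(ctx$y[sel])
  low <- sel[ctx$y[sel] <= ybot + 50 * shat]
  est <- ctx$clothing[def$part]; est[is.na(est)] <- 0
  list(point = c(mean(ctx$x[low]), ybot + 40 * shat,
                 quantile(ctx$z[low], 0.95) - est),
       rmse = 0)
}

# ear canal ~ head center: coronal position from the front head blob (top
# contour minus the measured head radius, since the chin is occluded by
# the neck), depth from the side view as the median over all silhouette
# pixels in the head-row band (a symmetric chord distribution centered on
# the head axis, free of classifier noise).
loc_ear <- function(def, ctx_side, ctx_front) {
  fsel <- if (!is.null(ctx_front)) part_sel(ctx_front, "head") else integer()
  if (length(fsel) < 10) stop("landmark unlocatable: ear_canal")
  xf <- median(ctx_front$x[fsel])
  rhat <- (quantile(ctx_front$x[fsel], 0.99) -
             quantile(ctx_front$x[fsel], 0.01)) / 2
  yf <- max(ctx_front$y[fsel]) - rhat
  ssel <- which(abs(ctx_side$y - yf) <= 40)
  if (length(ssel) < 10) stop("landmark unlocatable: ear_canal")
  list(point = c(xf, yf, median(ctx_side$z[ssel])), rmse = 0)
}

loc_asis <- function(def, ctx, shat, located) {
  cl <- located[["iliac_crest_mid_L"]]; cr <- located[["iliac_crest_mid_R"]]
  if (is.null(cl) || is.null(cr)) stop("landmark unlocatable: ", def$name)
  crest <- if (def$side > 0) cr$point else cl$point
  mid <- (cl$point + cr$point) / 2
  x0 <- mid[1] + 0.5 * (crest[1] - mid[1])
  y0 <- crest[2] - 40 * shat
  list(point = c(x0, y0, ctx_z_near(ctx, x0, y0)),
       rmse = max(cl$rmse, cr$rmse))
}

#' Locate one landmark in one frame
#'
#' Applies the definition's scan rule to the pixels of its part class:
#' back-projects them, fits a quadratic in the definition's plane and takes
#' the calibrated point at the fit's vertex, the band's topmost point or
#' the band midline; the depth coordinate is corrected toward the bone
#' surface by the per-part clothing estimate.
#'
#' @param def one entry of [landmark_registry()].
#' @param labeling [predict_parts()] output for the frame.
#' @param spmap [slic_segment()] output.
#' @param frame,camera the frame and camera.
#' @param mask the silhouette.
#' @param located named list of previously located landmarks (for
#'   dependent definitions).
#' @param ctx optional precomputed [view_context] (internal reuse).
#' @return `list(point = c(x, y, z), rmse = mm)`.
#' @export
locate_landmark <- function(def, labeling, spmap, frame, camera, mask,
                            located = list(), ctx = NULL) {
  if (is.null(ctx)) ctx <- view_context(frame, mask, spmap, labeling, camera)
  if (!def$part %in% ctx$cls) stop("landmark unlocatable: ", def$name)
  shat <- (max(ctx$y) - min(ctx$y)) / 1780
  res <- switch(def$strategy,
                contour_top = loc_contour_top(def, ctx, shat),
                shoulder = loc_shoulder(def, ctx, shat),
                c7 = loc_c7(def, ctx, shat),
                edge_profile = loc_edge_profile(def, ctx, shat),
                axis = loc_axis(def, ctx, shat, located),
                toe = loc_toe(def, ctx, shat),
                asis = loc_asis(def, ctx, shat, located),
                ear = stop("ear_canal needs two views; use locate_frame_skeleton"),
                stop("unknown strategy"))
  res$point <- as.numeric(res$point)
  res
}

#' Locate all landmarks of one synchronized frame triple
#'
#' @param ctxs named list of [view_context]s (`front`, `side`, `back`).
#' @param registry a [landmark_registry()].
#' @param frame_index integer tag.
#' @return object of class `frame_skeleton`: named list `points` (up to 28
#'   entries), `rmse`, `frame_index`.
#' @export
locate_frame_skeleton <- function(ctxs, registry = landmark_registry(),
                                  frame_index = 0L) {
  located <- list()
  shat_front <- if (!is.null(ctxs$front))
    (max(ctxs$front$y) - min(ctxs$front$y)) / 1780 else 1
  run_one <- function(def, ctx) {
    if (is.null(ctx)) stop("view missing")
    if (!def$part %in% ctx$cls) stop("landmark unlocatable: ", def$name)
    shat <- (max(ctx$y) - min(ctx$y)) / 1780
    switch(def$strategy,
           contour_top = loc_contour_top(def, ctx, shat),
           shoulder = loc_shoulder(def, ctx, shat),
           c7 = loc_c7(def, ctx, shat),
           edge_profile = loc_edge_profile(def, ctx, shat),
           axis = loc_axis(def, ctx, shat, located),
           toe = loc_toe(def, ctx, shat),
           asis = loc_asis(def, ctx, shat, located))
  }
  for (def in registry) {
    res <- tryCatch({
      if (def$strategy == "ear") {
        loc_ear(def, ctxs$side, ctxs$front)
      } else if (def$strategy %in% c("shoulder", "edge_profile")) {
        # these landmarks sit on the coronal mid-plane; the tangential
        # edge-depth errors (clothing, noise folding) have opposite signs
        # in the front and back views, so averaging both cancels them
        r1 <- run_one(def, ctxs[[def$view]])
        other <- if (def$view == "front") "back" else "front"
        r2 <- tryCatch(run_one(def, ctxs[[other]]), error = function(e) NULL)
        if (!is.null(r2) && all(is.finite(r2$point)))
          list(point = (r1$point + r2$point) / 2,
               rmse = max(r1$rmse, r2$rmse))
        else r1
      } else {
        run_one(def, ctxs[[def$view]])
      }
    }, error = function(e) NULL)
    if (!is.null(res) && all(is.finite(res$point)))
      located[[def$name]] <- res
  }
  structure(list(points = lapply(located, function(l) as.numeric(l$point)),
                 rmse = vapply(located, function(l) as.numeric(l$rmse)[1],
                               numeric(1)),
                 frame_index = as.integer(frame_index)),
            class = "frame_skeleton")
}

#' Average per-frame skeletons into the final 28-point skeleton
#'
#' Per landmark, frames whose fit RMSE exceeds `rmse_gate` are discarded
#' and the surviving positions are arithmetically averaged.  Every landmark
#' must survive in at least `min_valid` frames.
#'
#' @param frames list of `frame_skeleton`s.
#' @param min_valid minimum surviving frames per landmark.
#' @param rmse_gate RMSE gate in mm.
#' @return a [skeleton28()].
#' @export
aggregate_frames <- function(frames, min_valid = 5, rmse_gate = 25) {
  if (length(frames) < min_valid)
    stop("need at least min_valid = ", min_valid, " frames")
  pts <- list()
  for (nm in skeleton28_names()) {
    mat <- do.call(rbind, lapply(frames, function(f) {
      p <- f$points[[nm]]
      if (is.null(p) || f$rmse[[nm]] > rmse_gate) NULL else p
    }))
    if (is.null(mat) || nrow(mat) < min_valid)
      stop("landmark unstable: ", nm)
    pts[[nm]] <- colMeans(mat)
  }
  skeleton28(pts)
}
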