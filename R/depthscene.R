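#' Camera model for a fixed-position depth sensor
#'
#' Pinhole intrinsics plus the two scene distances that the positioning
#' hardware fixes: the nominal subject-to-camera distance and the distance of
#' the background wall.  All distances are in millimetres, focal lengths and
#' principal point in pixels.
#'
#' @param fx,fy focal lengths (px), must be positive.
#' @param cx,cy principal point (px).
#' @param capture_distance nominal subject distance (mm).
#' @param background_distance wall distance (mm); must exceed
#'   `capture_distance`.
#' @param height_above_floor height of the optical center over the floor
#'   plane (mm).  Plumbing needed to relate image rows to subject height; the
#'   default places a tripod-mounted sensor at chest height.
#' @return an object of class `camera_model`.
#' @export
camera_model <- function(fx = 580, fy = 580, cx = 320, cy = 240,
                         capture_distance = 2500,
                         background_distance = 4000,
                         height_above_floor = 900) {
  stopifnot(fx > 0, fy > 0)
  if (!(capture_distance > 0 && capture_distance < background_distance))
    stop("need 0 < capture_distance < background_distance")
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 capture_distance = capture_distance,
                 background_distance = background_distance,
                 height_above_floor = height_above_floor),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model> fx=%g fy=%g cx=%g cy=%g  subject at %g mm, wall at %g mm\n",
              x$fx, x$fy, x$cx, x$cy, x$capture_distance,
              x$background_distance))
  invisible(x)
}

#' A single depth frame
#'
#' @param z integer matrix of per-pixel depth (mm along the optical axis,
#'   rows = image rows); 0 means no sensor return.
#' @param view one of `"front"`, `"side"`, `"back"`.
#' @param frame_index integer frame number within the capture window.
#' @return an object of class `depth_frame` with fields `z`, `width`,
#'   `height`, `view`, `frame_index` and an `empty` flag.
#' @export
depth_frame <- function(z, view, frame_index = 0L) {
  view <- match.arg(view, c("front", "side", "back"))
  z <- as.matrix(z)
  storage.mode(z) <- "integer"
  if (nrow(z) < 1 || ncol(z) < 1) stop("width, height must be positive")
  if (any(z < 0, na.rm = TRUE)) stop("depths must be >= 0")
  structure(list(z = z, width = ncol(z), height = nrow(z), view = view,
                 frame_index = as.integer(frame_index),
                 empty = all(z == 0L)),
            class = "depth_frame")
}

#' @export
print.depth_frame <- function(x, ...) {
  cat(sprintf("<depth_frame> %s #%d, %dx%d px, depth %d..%d mm%s\n",
              x$view, x$frame_index, x$width, x$height,
              min(x$z), max(x$z), if (x$empty) " (empty)" else ""))
  invisible(x)
}

# Rigid transforms between the subject frame (x = anatomical right, y = up
# from the floor, z = anterior) and the camera frame of each view (Xc right
# in image, Yc up, Zc along the optical axis).  The subject faces the camera
# in the front view, so the image is mirrored (+x is the viewer's left); the
# side view has the camera on the subject's right, so anterior maps to +Xc
# and the depth axis measures the mediolateral coordinate.
subject_to_camera <- function(p, view, camera) {
  D <- camera$capture_distance
  hh <- camera$height_above_floor
  switch(view,
    front = cbind(-p[, 1], p[, 2] - hh, D - p[, 3]),
    back  = cbind(p[, 1], p[, 2] - hh, D + p[, 3]),
    side  = cbind(p[, 3], p[, 2] - hh, D - p[, 1]))
}

camera_to_subject <- function(q, view, camera) {
  D <- camera$capture_distance
  hh <- camera$height_above_floor
  switch(view,
    front = cbind(-q[, 1], q[, 2] + hh, D - q[, 3]),
    back  = cbind(q[, 1], q[, 2] + hh, q[, 3] - D),
    side  = cbind(D - q[, 3], q[, 2] + hh, q[, 1]))
}

#' Back-project a pixel to subject-frame coordinates
#'
#' Pixel coordinates are zero-based (`u = cx`, `v = cy` is the principal
#' ray).  The depth stored at the pixel is interpreted as z-depth along the
#' optical axis, the convention of structured-light sensors.
#'
#' @param frame a [depth_frame()].
#' @param camera a [camera_model()].
#' @param u,v pixel coordinates (vectors allowed).
#' @return matrix with columns `x`, `y`, `z` (mm, subject frame).
#' @export
pixel_to_world <- function(frame, camera, u, v) {
  z <- frame$z[cbind(round(v) + 1L, round(u) + 1L)]
  if (any(z <= 0)) stop("no return at pixel")
  pixel_to_world_z(camera, u, v, as.numeric(z), frame$view)
}

# back-projection when the depth values are already at hand (possibly
# sub-pixel or corrected)
pixel_to_world_z <- function(camera, u, v, z, view) {
  Xc <- (u - camera$cx) * z / camera$fx
  Yc <- (camera$cy - v) * z / camera$fy
  p <- camera_to_subject(cbind(Xc, Yc, z), view, camera)
  colnames(p) <- c("x", "y", "z")
  p
}

#' Project subject-frame points into a view
#'
#' Inverse of [pixel_to_world()]; returns fractional pixel coordinates and
#' the z-depth each point would have.
#'
#' @param p numeric matrix (or length-3 vector) of subject-frame points, mm.
#' @inheritParams pixel_to_world
#' @param view `"front"`, `"side"` or `"back"`.
#' @return matrix with columns `u`, `v`, `z`.
#' @export
world_to_pixel <- function(p, camera, view) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  q <- subject_to_camera(p, view, camera)
  out <- cbind(u = camera$cx + camera$fx * q[, 1] / q[, 3],
               v = camera$cy - camera$fy * q[, 2] / q[, 3],
               z = q[, 3])
  out
}

camera_to_json <- function(camera, view, frame_index) {
  jsonlite::toJSON(list(view = view, frame_index = frame_index,
                        fx = camera$fx, fy = camera$fy, cx = camera$cx,
                        cy = camera$cy,
                        capture_distance = camera$capture_distance,
                        background_distance = camera$background_distance,
                        height_above_floor = camera$height_above_floor),
                   auto_unbox = TRUE, digits = NA)
}

#' Write / read a depth frame as 16-bit PNG plus JSON sidecar
#'
#' One digital number is one millimetre of depth; the encoding is lossless
#' 16-bit single-channel PNG.  The sidecar `<path>.json` carries the view,
#' frame index and camera fields.
#'
#' @inheritParams pixel_to_world
#' @param path PNG file path.
#' @return `read_depth_frame` returns `list(frame, camera)`.
#' @export
write_depth_frame <- function(frame, camera, path) {
  .png16_write(path, frame$z)
  writeLines(camera_to_json(camera, frame$view, frame$frame_index),
             paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_depth_frame
#' @export
read_depth_frame <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("camera metadata required: missing ", sidecar)
  meta <- jsonlite::fromJSON(sidecar)
  z <- .png16_read(path)
  frame <- depth_frame(z, view = meta$view,
                       frame_index = meta$frame_index)
  camera <- camera_model(meta$fx, meta$fy, meta$cx, meta$cy,
                         meta$capture_distance, meta$background_distance,
                         if (is.null(meta$height_above_floor)) 900
                         else meta$height_above_floor)
  list(frame = frame, camera = camera)
}

#' A complete capture session
#'
#' Frames for the three views over the 2-3 s capture window plus one
#' background reference frame per view and the camera model.
#'
#' @param frames named list `front` / `side` / `back`, each a list of
#'   [depth_frame()]s (at least one per view, equal dimensions per view).
#' @param background named list of background [depth_frame()]s per view.
#' @param camera a [camera_model()].
#' @export
capture_session <- function(frames, background, camera) {
  for (v in c("front", "side", "back")) {
    if (is.null(frames[[v]]) || length(frames[[v]]) < 1)
      stop("incomplete session: ", v)
    dims <- vapply(frames[[v]], function(f) c(f$height, f$width), numeric(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("frame dimensions differ within view ", v)
    if (is.null(background[[v]])) stop("missing background for view ", v)
  }
  structure(list(frames = frames, background = background, camera = camera),
            class = "capture_session")
}

#' @export
print.capture_session <- function(x, ...) {
  n <- vapply(x$frames, length, integer(1))
  cat(sprintf("<capture_session> %d/%d/%d frames (front/side/back), %dx%d px\n",
              n[["front"]], n[["side"]], n[["back"]],
              x$frames$front[[1]]$width, x$frames$front[[1]]$height))
  invisible(x)
}

#' Write / read a capture session directory
#'
#' Layout: `<view>_<index>.png(.json)` for frames,
#' `background_<view>.png(.json)` for backgrounds.
#'
#' @param session a [capture_session()].
#' @param dir directory (created if needed).
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (v in c("front", "side", "back")) {
    for (f in session$frames[[v]])
      write_depth_frame(f, session$camera,
                        file.path(dir, sprintf("%s_%03d.png", v, f$frame_index)))
    write_depth_frame(session$background[[v]], session$camera,
                      file.path(dir, sprintf("background_%s.png", v)))
  }
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  frames <- list()
  background <- list()
  camera <- NULL
  for (v in c("front", "side", "back")) {
    paths <- sort(list.files(dir, sprintf("^%s_\\d+\\.png$", v),
                             full.names = TRUE))
    if (length(paths) == 0) stop("incomplete session: ", v)
    frames[[v]] <- lapply(paths, function(p) {
      fr <- read_depth_frame(p)
      camera <<- fr$camera
      fr$frame
    })
    bg <- read_depth_frame(file.path(dir, sprintf("background_%s.png", v)))
    background[[v]] <- bg$frame
  }
  capture_session(frames, background, camera)
}
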