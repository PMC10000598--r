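#' Extract the subject silhouette by depth background subtraction
#'
#' Candidate pixels are those with a valid return that stand out from the
#' background reference by more than `tau` and lie within the expected
#' depth band around the capture distance.  The largest 4-connected
#' candidate component is kept and its interior holes (depth dropout) are
#' filled before the minimum-area test.
#'
#' @param frame,background [depth_frame()]s of the same view and size.
#' @param tau foreground threshold (mm): background depth minus frame depth
#'   must exceed it.
#' @param z_band `c(lo, hi)` in mm; defaults to the capture distance
#'   +/- 600 mm.
#' @param min_area minimum silhouette area in pixels.
#' @param camera optional [camera_model()] used for the `z_band` default.
#' @return object of class `silhouette_mask`: logical `mask`, `view`,
#'   `pixel_count`.
#' @export
extract_silhouette <- function(frame, background, tau = 100,
                               z_band = NULL, min_area = 2000,
                               camera = NULL) {
  stopifnot(tau > 0)
  if (frame$width != background$width || frame$height != background$height)
    stop("frame/background mismatch")
  if (is.null(z_band)) {
    d <- if (!is.null(camera)) camera$capture_distance else
      stats::median(background$z[background$z > 0]) - 1500
    z_band <- c(d - 600, d + 600)
  }
  z <- frame$z
  cand <- (background$z - z > tau) & (z > 0) &
    (z >= z_band[1]) & (z <= z_band[2])
  if (!any(cand)) stop("no subject detected")
  # work inside the candidate bounding box (with a 1 px margin) -- the
  # morphology is linear in pixel count
  rr <- range(which(rowSums(cand) > 0)); cr <- range(which(colSums(cand) > 0))
  r0 <- max(rr[1] - 1, 1); r1 <- min(rr[2] + 1, nrow(cand))
  c0 <- max(cr[1] - 1, 1); c1 <- min(cr[2] + 1, ncol(cand))
  sub <- cand[r0:r1, c0:c1, drop = FALSE]
  cc <- .cc_label(sub)
  keep <- which.max(cc$sizes)
  subm <- .fill_holes(cc$labels == keep)
  mask <- matrix(FALSE, nrow(cand), ncol(cand))
  mask[r0:r1, c0:c1] <- subm
  if (sum(mask) < min_area) stop("no subject detected")
  structure(list(mask = mask, view = frame$view, pixel_count = sum(mask)),
            class = "silhouette_mask")
}

#' @export
print.silhouette_mask <- function(x, ...) {
  cat(sprintf("<silhouette_mask> %s view, %d px\n", x$view, x$pixel_count))
  invisible(x)
}

#' Write a silhouette mask as an 8-bit-range PNG (debug aid)
#' @param sil a `silhouette_mask`.
#' @param path output path.
#' @export
write_mask_png <- function(sil, path) {
  .png16_write(path, matrix(as.integer(sil$mask) * 65535L,
                            nrow(sil$mask), ncol(sil$mask)))
  invisible(path)
}
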