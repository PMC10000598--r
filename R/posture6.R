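#' @name posture6
#' @title Six postural outcome parameters
#'
#' @description
#' The six outcomes measured on a standing subject, with the device's sign
#' convention: negative values mean that the left side is raised or that the
#' posture is tilted to the left; a positive forward-head angle means the
#' head is anterior.  Subject-frame coordinates are x = anatomical right,
#' y = up, z = anterior, in mm.
#'
#' * asymmetric clavicle height (deg) - angle between the horizontal and
#'   the line joining the highest clavicle points;
#' * pelvic obliquity (deg and mm) - elevation angle / signed height
#'   difference of the iliac-crest midpoints;
#' * right and left Q angle (deg) - coronal angle between the ASIS-patella
#'   line and the tibial-tuberosity-patella line, positive = valgus;
#' * C7-CSL (mm and deg) - offset of the C7 center from the central sacral
#'   vertical line;
#' * forward head posture (deg) - sagittal inclination of the C7-to-ear-canal
#'   line from the vertical.
NULL

rad2deg <- function(r) r * 180 / pi
deg2rad <- function(d) d * pi / 180

pt_xyz <- function(p) {
  p <- as.numeric(p)
  stopifnot(length(p) == 3, all(is.finite(p)))
  p
}

#' Elevation angle of a left/right landmark pair
#'
#' Angle between the horizontal and the line from the left landmark to the
#' right landmark, in the coronal (x, y) plane.  Negative iff the left side
#' is higher.
#'
#' @param left,right subject-frame points `c(x, y, z)` in mm; `right` must
#'   have the larger x.
#' @return angle in degrees.
#' @export
elevation_angle <- function(left, right) {
  left <- pt_xyz(left); right <- pt_xyz(right)
  if (!(right[1] > left[1])) stop("degenerate landmark pair")
  rad2deg(atan2(right[2] - left[2], right[1] - left[1]))
}

#' Signed coronal Q angle
#'
#' `180 deg` minus the angle between `patella - asis` and
#' `patella - tibial_tub`, projected to the coronal plane; the sign is
#' positive when the ASIS-to-patella line deviates laterally (valgus) from
#' the extension of the tibial_tub-to-patella line, on either limb.
#'
#' @param asis,patella,tibial_tub subject-frame points, mm.
#' @param side `"R"` or `"L"`.
#' @return signed angle in degrees.
#' @export
q_angle <- function(asis, patella, tibial_tub, side = c("R", "L")) {
  side <- match.arg(side)
  asis <- pt_xyz(asis); patella <- pt_xyz(patella)
  tibial_tub <- pt_xyz(tibial_tub)
  u <- patella[1:2] - asis[1:2]        # thigh-line direction
  v <- patella[1:2] - tibial_tub[1:2]  # patellar tendon, pointing up
  if (sqrt(sum(u^2)) < 1e-9 || sqrt(sum(v^2)) < 1e-9)
    stop("degenerate landmark triplet")
  w <- -v                              # tendon line extended through patella
  cross <- w[1] * u[2] - w[2] * u[1]
  dot <- sum(w * u)
  signed <- rad2deg(atan2(cross, dot))
  if (side == "L") -signed else signed
}

#' Trunk offset: C7 versus the central sacral vertical line
#'
#' @param c7,sacrum subject-frame points, mm; C7 must lie above the sacrum.
#' @return `c(mm = , deg = )`: the signed horizontal offset of C7 from the
#'   vertical through the sacrum center, and the inclination of the
#'   C7-sacrum line.  Negative = tilted to the left.
#' @export
trunk_offset <- function(c7, sacrum) {
  c7 <- pt_xyz(c7); sacrum <- pt_xyz(sacrum)
  if (!(c7[2] > sacrum[2])) stop("implausible skeleton: C7 not above sacrum")
  c(mm = c7[1] - sacrum[1],
    deg = rad2deg(atan2(c7[1] - sacrum[1], c7[2] - sacrum[2])))
}

#' Forward head posture angle
#'
#' Sagittal inclination of the C7-to-ear-canal line from the vertical;
#' positive when the head is anterior.
#'
#' @param c7,ear subject-frame points, mm; the ear must lie above C7.
#' @return angle in degrees.
#' @export
forward_head <- function(c7, ear) {
  c7 <- pt_xyz(c7); ear <- pt_xyz(ear)
  if (!(ear[2] > c7[2])) stop("implausible skeleton: ear not above C7")
  rad2deg(atan2(ear[3] - c7[3], ear[2] - c7[2]))
}

#' Compute all six posture parameters from a 28-point skeleton
#'
#' @param skeleton a [skeleton28()] (named list of `c(x, y, z)` points).
#' @param variant `"clinical"` (default) computes pelvic obliquity as a
#'   vertical height difference and C7-CSL as a horizontal plumbline offset;
#'   `"literal"` swaps the two distance axes, reproducing the alternative
#'   literal reading of the outcome definitions (exposed for comparison,
#'   not endorsed).
#' @return object of class `posture_parameters`: `clavicle_asym_deg`,
#'   `pelvic_oblique_deg`, `pelvic_oblique_mm`, `q_right_deg`, `q_left_deg`,
#'   `c7_csl_deg`, `c7_csl_mm`, `fhp_deg`.
#' @export
compute_posture <- function(skeleton, variant = c("clinical", "literal")) {
  variant <- match.arg(variant)
  s <- skeleton
  need <- c("clavicle_highest_L", "clavicle_highest_R", "iliac_crest_mid_L",
            "iliac_crest_mid_R", "ASIS_L", "ASIS_R", "patella_center_L",
            "patella_center_R", "tibial_tuberosity_L", "tibial_tuberosity_R",
            "C7_center", "sacrum_center", "ear_canal")
  miss <- setdiff(need, names(s))
  if (length(miss)) stop("missing landmark: ", paste(miss, collapse = ", "))
  trunk <- trunk_offset(s$C7_center, s$sacrum_center)
  pelv_mm <- if (variant == "clinical")
    s$iliac_crest_mid_R[2] - s$iliac_crest_mid_L[2]
  else
    s$iliac_crest_mid_R[1] - s$iliac_crest_mid_L[1]
  csl_mm <- if (variant == "clinical") unname(trunk["mm"])
  else s$C7_center[2] - s$sacrum_center[2]
  out <- list(
    clavicle_asym_deg = elevation_angle(s$clavicle_highest_L,
                                        s$clavicle_highest_R),
    pelvic_oblique_deg = elevation_angle(s$iliac_crest_mid_L,
                                         s$iliac_crest_mid_R),
    pelvic_oblique_mm = pelv_mm,
    q_right_deg = q_angle(s$ASIS_R, s$patella_center_R,
                          s$tibial_tuberosity_R, "R"),
    q_left_deg = q_angle(s$ASIS_L, s$patella_center_L,
                         s$tibial_tuberosity_L, "L"),
    c7_csl_deg = unname(trunk["deg"]),
    c7_csl_mm = csl_mm,
    fhp_deg = forward_head(s$C7_center, s$ear_canal))
  structure(out, class = "posture_parameters", variant = variant)
}

#' The six outcome names
#' @return character vector of the six outcome identifiers.
#' @export
posture_parameter_names <- function() {
  c("clavicle_asym_deg", "pelvic_oblique_deg", "q_right_deg", "q_left_deg",
    "c7_csl_mm", "fhp_deg")
}

#' @export
print.posture_parameters <- function(x, ...) {
  cat("<posture_parameters>\n")
  cat(sprintf("  asymmetric clavicle height: %7.2f deg\n", x$clavicle_asym_deg))
  cat(sprintf("  pelvic obliquity:           %7.2f deg (%.1f mm)\n",
              x$pelvic_oblique_deg, x$pelvic_oblique_mm))
  cat(sprintf("  Q angle right / left:       %7.2f / %.2f deg\n",
              x$q_right_deg, x$q_left_deg))
  cat(sprintf("  C7-CSL:                     %7.1f mm (%.2f deg)\n",
              x$c7_csl_mm, x$c7_csl_deg))
  cat(sprintf("  forward head posture:       %7.2f deg\n", x$fhp_deg))
  invisible(x)
}

#' @export
as.data.frame.posture_parameters <- function(x, ...) {
  data.frame(parameter = c("clavicle_asym", "pelvic_oblique", "q_right",
                           "q_left", "c7_csl", "fhp"),
             value = c(x$clavicle_asym_deg, x$pelvic_oblique_deg,
                       x$q_right_deg, x$q_left_deg, x$c7_csl_mm, x$fhp_deg),
             unit = c("deg", "deg", "deg", "deg", "mm", "deg"))
}
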