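test_that("elevation angle follows its closed form and sign convention", {
  expect_equal(elevation_angle(c(-180, 1400, 0), c(180, 1400, 0)), 0)
  # left raised 10 mm over a 360 mm span: negative
  a <- elevation_angle(c(-180, 1410, 0), c(180, 1400, 0))
  expect_equal(a, -atan(10 / 360) * 180 / pi, tolerance = 1e-12)
  expect_equal(a, -1.591, tolerance = 1e-3)
  expect_equal(elevation_angle(c(-180, 1400, 0), c(180, 1410, 0)), -a)
  expect_error(elevation_angle(c(0, 1, 0), c(0, 2, 0)), "degenerate")
})

test_that("q_angle matches an independent two-atan2 oracle", {
  # collinear: zero
  expect_equal(q_angle(c(90, 900, 0), c(90, 500, 0), c(90, 420, 0), "R"), 0)

  asis <- c(80, 900, 0); pat <- c(110, 500, 0); tib <- c(100, 420, 0)
  q <- q_angle(asis, pat, tib, "R")
  # oracle: difference of the two line directions
  ang_u <- atan2(pat[2] - asis[2], pat[1] - asis[1])
  ang_w <- atan2(tib[2] - pat[2], tib[1] - pat[1])  # tendon extension
  d <- (ang_w - ang_u) * 180 / pi
  d <- ((d + 180) %% 360) - 180
  expect_equal(q, -d, tolerance = 1e-9)

  # mirroring all x and swapping side preserves the signed value
  m <- function(p) c(-p[1], p[2], p[3])
  expect_equal(q_angle(m(asis), m(pat), m(tib), "L"), q, tolerance = 1e-12)
  expect_error(q_angle(asis, asis, tib, "R"), "degenerate")
})

test_that("trunk offset returns both units with the left-negative sign", {
  expect_equal(trunk_offset(c(0, 1470, 0), c(0, 1020, 0)),
               c(mm = 0, deg = 0))
  to <- trunk_offset(c(-13, 1520, 0), c(0, 1020, 0))
  expect_equal(unname(to["mm"]), -13)
  expect_equal(unname(to["deg"]), -atan(13 / 500) * 180 / pi,
               tolerance = 1e-12)
  expect_equal(unname(to["deg"]), -1.489, tolerance = 1e-3)
  # doubling the rise halves the angle (small angles), mm unchanged
  to2 <- trunk_offset(c(-13, 2020, 0), c(0, 1020, 0))
  expect_equal(unname(to2["mm"]), -13)
  expect_equal(unname(to2["deg"]), unname(to["deg"]) / 2, tolerance = 1e-3)
  expect_error(trunk_offset(c(0, 100, 0), c(0, 1020, 0)), "implausible")
})

test_that("forward head angle follows its closed form", {
  expect_equal(forward_head(c(0, 1470, -55), c(0, 1590, -55)), 0)
  expect_equal(forward_head(c(0, 1470, -55), c(0, 1590, -55 + 16.65)),
               7.9, tolerance = 1e-3)
  expect_lt(forward_head(c(0, 1470, -55), c(0, 1590, -70)), 0)
  expect_error(forward_head(c(0, 1590, 0), c(0, 1470, 0)), "implausible")
})

test_that("compute_posture returns exactly six named outcomes", {
  gt <- build_skeleton(subject_params())
  pp <- compute_posture(gt$skeleton)
  expect_s3_class(pp, "posture_parameters")
  expect_equal(posture_parameter_names(),
               c("clavicle_asym_deg", "pelvic_oblique_deg", "q_right_deg",
                 "q_left_deg", "c7_csl_mm", "fhp_deg"))
  for (nm in posture_parameter_names()) expect_equal(pp[[nm]], 0)
  expect_equal(nrow(as.data.frame(pp)), 6)
})

test_that("mirror antisymmetry holds for all outcomes", {
  p <- random_subject_params(seed = 77)
  s <- build_skeleton(p)$skeleton
  m <- unclass(s)
  swap <- function(nm) {
    if (grepl("_L$", nm)) sub("_L$", "_R", nm)
    else if (grepl("_R$", nm)) sub("_R$", "_L", nm) else nm
  }
  sm <- stats::setNames(
    lapply(names(m), function(nm) {
      q <- m[[swap(nm)]]; q["x"] <- -q["x"]; q
    }), names(m))
  ppm <- compute_posture(skeleton28(sm))
  pp <- compute_posture(s)
  expect_equal(ppm$clavicle_asym_deg, -pp$clavicle_asym_deg, tolerance = 1e-9)
  expect_equal(ppm$pelvic_oblique_deg, -pp$pelvic_oblique_deg, tolerance = 1e-9)
  expect_equal(ppm$pelvic_oblique_mm, -pp$pelvic_oblique_mm, tolerance = 1e-9)
  expect_equal(ppm$c7_csl_mm, -pp$c7_csl_mm, tolerance = 1e-9)
  expect_equal(ppm$c7_csl_deg, -pp$c7_csl_deg, tolerance = 1e-9)
  expect_equal(ppm$fhp_deg, pp$fhp_deg, tolerance = 1e-9)
  expect_equal(ppm$q_right_deg, pp$q_left_deg, tolerance = 1e-9)
  expect_equal(ppm$q_left_deg, pp$q_right_deg, tolerance = 1e-9)
})

test_that("angles are translation and scale invariant; mm scale linearly", {
  p <- random_subject_params(seed = 31)
  s <- build_skeleton(p)$skeleton
  pp <- compute_posture(s)
  tr <- lapply(unclass(s), function(q) (q + c(40, 90, -20)) * 2)
  ppt <- compute_posture(skeleton28(tr))
  for (nm in c("clavicle_asym_deg", "pelvic_oblique_deg", "q_right_deg",
               "q_left_deg", "c7_csl_deg", "fhp_deg"))
    expect_equal(ppt[[nm]], pp[[nm]], tolerance = 1e-9)
  # the translation has no x component, so mm outputs scale by exactly 2
  expect_equal(ppt$pelvic_oblique_mm, 2 * pp$pelvic_oblique_mm,
               tolerance = 1e-9)
  expect_equal(ppt$c7_csl_mm, 2 * pp$c7_csl_mm, tolerance = 1e-9)
})

test_that("the literal-text variant swaps the two distance axes", {
  p <- random_subject_params(seed = 5)
  s <- build_skeleton(p)$skeleton
  lit <- compute_posture(s, variant = "literal")
  expect_equal(lit$pelvic_oblique_mm,
               s$iliac_crest_mid_R["x"] - s$iliac_crest_mid_L["x"],
               ignore_attr = TRUE)
  expect_equal(lit$c7_csl_mm, s$C7_center["y"] - s$sacrum_center["y"],
               ignore_attr = TRUE)
})
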