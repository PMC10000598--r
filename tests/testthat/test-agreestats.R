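# independent from-definition oracle for ICC(2,1): explicit ANOVA sums
icc21_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  gm <- mean(m)
  MSR <- k * sum((rowMeans(m) - gm)^2) / (n - 1)
  MSC <- n * sum((colMeans(m) - gm)^2) / (k - 1)
  SST <- sum((m - gm)^2)
  SSE <- SST - k * sum((rowMeans(m) - gm)^2) - n * sum((colMeans(m) - gm)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
}

test_that("icc_single matches the brute-force ANOVA oracle", {
  m <- matrix(c(1, 3, 5, 7, 2, 4, 6, 8), ncol = 2)
  r <- icc_single(m)
  expect_equal(r$estimate, icc21_oracle(m), tolerance = 1e-9)
  expect_true(r$ci_low <= r$estimate && r$estimate <= r$ci_high)
  expect_equal(r$n, 4)
  expect_equal(r$k, 2)

  set.seed(21)
  for (i in 1:10) {
    m <- matrix(rnorm(40, sd = 2) + rep(rnorm(20, sd = 3), 2), ncol = 2)
    expect_equal(icc_single(m)$estimate, icc21_oracle(m), tolerance = 1e-9)
  }
})

test_that("identical columns give an ICC of exactly 1", {
  x <- c(3, 9, 1, 7, 5)
  r <- icc_single(x, x)
  expect_equal(r$estimate, 1)
  expect_error(icc_single(rep(1, 5), rep(1, 5)), "degenerate data")
})

test_that("the ICC estimate is consistent for its variance ratio", {
  set.seed(33)
  n <- 1000; sb <- 2; sw <- 1
  subj <- rnorm(n, sd = sb)
  m <- cbind(subj + rnorm(n, sd = sw), subj + rnorm(n, sd = sw))
  expect_lt(abs(icc_single(m)$estimate - sb^2 / (sb^2 + sw^2)), 0.02)
})

test_that("icc_single is invariant to shift and positive scaling", {
  set.seed(4)
  m <- matrix(rnorm(30) + rep(rnorm(15), 2), ncol = 2)
  r0 <- icc_single(m)$estimate
  expect_equal(icc_single(m + 100)$estimate, r0, tolerance = 1e-9)
  expect_equal(icc_single(m * 7)$estimate, r0, tolerance = 1e-9)
})

test_that("with no subject variance the CI covers zero at its level", {
  set.seed(9)
  cover <- vapply(1:1000, function(i) {
    m <- matrix(rnorm(60), ncol = 2)
    r <- icc_single(m)
    r$ci_low <= 0 && 0 <= r$ci_high
  }, logical(1))
  expect_gte(mean(cover), 0.93)
})

test_that("pearson_corr matches the definition and handles edge cases", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 6)
  r <- pearson_corr(x, y)
  # from-definition oracle with explicit sums
  cx <- x - mean(x); cy <- y - mean(y)
  r_o <- sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
  expect_equal(r$r, r_o, tolerance = 1e-12)
  t_o <- r_o * sqrt(3 / (1 - r_o^2))
  expect_equal(r$p, 2 * pt(abs(t_o), 3, lower.tail = FALSE),
               tolerance = 1e-12)

  expect_equal(pearson_corr(x, x)$r, 1)
  expect_equal(pearson_corr(x, -x)$r, -1)
  expect_error(pearson_corr(x, rep(2, 5)), "zero variance input")
  expect_error(pearson_corr(1:2, 2:3), "at least 3")
})

test_that("pearson_corr is affine-equivariant", {
  set.seed(12)
  x <- rnorm(25); y <- x + rnorm(25)
  r0 <- pearson_corr(x, y)$r
  expect_equal(pearson_corr(3 * x + 7, y)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_corr(x, 0.5 * y - 2)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_corr(-2 * x, y)$r, -r0, tolerance = 1e-12)
})

test_that("paired_t matches its hand formula", {
  x <- c(5, 5, 5, 5)
  expect_equal(paired_t(x, x)$t, 0)
  expect_equal(paired_t(x, x)$p, 1)

  d <- c(1, -1, 1, -1)
  expect_equal(paired_t(d, rep(0, 4))$t, 0)

  d <- 1:5
  r <- paired_t(d, rep(0, 5))
  expect_equal(r$t, 3 * sqrt(5) / sqrt(2.5), tolerance = 1e-12)
  expect_equal(r$df, 4)

  expect_error(paired_t(c(2, 3, 4), c(1, 2, 3)), "degenerate differences")
})

test_that("reliability banding reproduces the published rule", {
  expect_equal(band_reliability(0.84), "excellent")
  expect_equal(band_reliability(0.75), "fair-to-good")  # boundary inclusive
  expect_equal(band_reliability(0.76), "excellent")
  expect_equal(band_reliability(0.4), "fair-to-good")
  expect_equal(band_reliability(0.39), "poor")
  expect_equal(band_reliability(c(0.69, 0.84)),
               c("fair-to-good", "excellent"))
})

test_that("correlation banding reproduces the published rule on |r|", {
  expect_equal(band_correlation(0.42), "moderate")
  expect_equal(band_correlation(0.37), "fair")
  expect_equal(band_correlation(-0.15), "poor")
  expect_equal(band_correlation(0.20), "poor")
  expect_equal(band_correlation(0.21), "fair")
  expect_equal(band_correlation(0.40), "fair")
  expect_equal(band_correlation(0.41), "moderate")
  expect_equal(band_correlation(0.60), "moderate")
  expect_equal(band_correlation(0.61), "good")
  expect_equal(band_correlation(0.80), "good")
  expect_equal(band_correlation(0.81), "excellent")
  expect_equal(band_correlation(1.00), "excellent")
  # rounding happens before banding
  expect_equal(band_correlation(0.404), "fair")
})

test_that("report builders emit one row per parameter", {
  set.seed(14)
  params <- posture_parameter_names()
  rel <- do.call(rbind, lapply(params, function(p) {
    base <- rnorm(12)
    data.frame(parameter = p, measurement_1 = base + rnorm(12, 0, 0.3),
               measurement_2 = base + rnorm(12, 0, 0.3))
  }))
  val <- do.call(rbind, lapply(params, function(p) {
    base <- rnorm(12)
    data.frame(parameter = p, device_a = base + rnorm(12, 0, 0.5),
               device_b = base + rnorm(12, 0, 0.5))
  }))
  rep <- build_reports(paired = rel, device_pairs = val)
  expect_equal(nrow(rep$reliability), 6)
  expect_equal(nrow(rep$validity), 6)
  expect_true(all(rep$reliability$band %in%
                    c("excellent", "fair-to-good", "poor")))

  # duplicate columns: all ICCs exactly 1 and excellent
  rel$measurement_2 <- rel$measurement_1
  rr <- reliability_report(rel)
  expect_true(all(rr$icc == 1))
  expect_true(all(rr$band == "excellent"))

  # cells agree with the per-operation oracles
  one <- val[val$parameter == params[1], ]
  expect_equal(rep$validity$r[1], pearson_corr(one$device_a, one$device_b)$r,
               tolerance = 1e-12)
  m <- rel[rel$parameter == params[1], ]
  expect_equal(rr$icc[1], icc21_oracle(cbind(m$measurement_1,
                                             m$measurement_2)),
               tolerance = 1e-9)
})
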