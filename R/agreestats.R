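#' Intra-rater intraclass correlation, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measures ICC from the
#' ANOVA mean squares of an n-subjects-by-k-measurements table, with the
#' 95% confidence interval from the F-distribution formulas for that form.
#' The form tag is recorded in the result so reports are explicit about
#' the model.
#'
#' @param x numeric matrix (subjects x measurements, k >= 2 columns) or the
#'   first measurement vector.
#' @param y second measurement vector when `x` is a vector.
#' @param conf confidence level.
#' @return object of class `icc_result`: `estimate`, `ci_low`, `ci_high`,
#'   `form`, `n`, `k`, `p`.
#' @export
icc_single <- function(x, y = NULL, conf = 0.95) {
  m <- if (is.null(y)) as.matrix(x) else cbind(x, y)
  if (any(!is.finite(m))) stop("missing cells not allowed")
  n <- nrow(m); k <- ncol(m)
  if (n < 3) stop("need at least 3 subjects")
  if (k < 2) stop("need at least 2 measurements")
  gm <- mean(m)
  if (sum((m - gm)^2) < 1e-24) stop("degenerate data")
  rowm <- rowMeans(m); colm <- colMeans(m)
  MSR <- k * sum((rowm - gm)^2) / (n - 1)
  MSC <- n * sum((colm - gm)^2) / (k - 1)
  SSE <- sum((m - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) + gm)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)

  # McGraw & Wong confidence bounds for the agreement form
  alpha <- 1 - conf
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  FL <- qf(1 - alpha / 2, n - 1, v)
  FU <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  upper <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  p <- pf(MSR / MSE, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  structure(list(estimate = icc, ci_low = lower, ci_high = upper,
                 form = "ICC(2,1) absolute agreement, single measures",
                 n = n, k = k, p = p),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC = %.3f [%.3f, %.3f] (%s, n = %d, k = %d, p = %.3g)\n",
              x$estimate, x$ci_low, x$ci_high, x$form, x$n, x$k, x$p))
  invisible(x)
}

#' Pearson correlation with two-sided t-test
#'
#' @param x,y equal-length numeric vectors, both non-constant, n >= 3.
#' @return object of class `corr_result`: `r`, `p`, `n`.
#' @export
pearson_corr <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance input")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tt), n - 2, lower.tail = FALSE)
  structure(list(r = r, p = min(p, 1), n = n), class = "corr_result")
}

#' @export
print.corr_result <- function(x, ...) {
  cat(sprintf("r = %.3f (n = %d, p = %.3g)\n", x$r, x$n, x$p))
  invisible(x)
}

#' Paired t-test
#'
#' @param x,y paired measurement vectors, n >= 2.
#' @return object of class `ttest_result`: `t`, `df`, `p`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 2) stop("need at least 2 pairs")
  d <- x - y
  if (sd(d) == 0) {
    if (all(d == 0))
      return(structure(list(t = 0, df = n - 1, p = 1),
                       class = "ttest_result"))
    stop("degenerate differences")
  }
  tt <- mean(d) / (sd(d) / sqrt(n))
  structure(list(t = tt, df = n - 1,
                 p = 2 * pt(abs(tt), n - 1, lower.tail = FALSE)),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, p = %.3g\n", x$df, x$t, x$p))
  invisible(x)
}

#' Qualitative reliability band for an ICC value
#'
#' `> 0.75` excellent, `0.4`-`0.75` fair-to-good (boundaries inclusive),
#' `< 0.4` poor.
#'
#' @param icc ICC value (at most 1).
#' @return `"excellent"`, `"fair-to-good"` or `"poor"`.
#' @export
band_reliability <- function(icc) {
  stopifnot(all(icc <= 1 + 1e-12))
  ifelse(icc > 0.75, "excellent",
         ifelse(icc >= 0.4, "fair-to-good", "poor"))
}

#' Qualitative strength band for a correlation coefficient
#'
#' Applied to `|r|` after rounding to two decimals: 0.00-0.20 poor,
#' 0.21-0.40 fair, 0.41-0.60 moderate, 0.61-0.80 good, 0.81-1.00
#' excellent.
#'
#' @param r correlation in `[-1, 1]`.
#' @return band label.
#' @export
band_correlation <- function(r) {
  stopifnot(all(abs(r) <= 1 + 1e-12))
  a <- round(abs(r), 2)
  ifelse(a <= 0.20, "poor",
         ifelse(a <= 0.40, "fair",
                ifelse(a <= 0.60, "moderate",
                       ifelse(a <= 0.80, "good", "excellent"))))
}

#' Reliability and validity report tables
#'
#' `reliability_report` takes repeated-measurement pairs per parameter and
#' returns one row per parameter with the ICC, its confidence interval,
#' the significance and the qualitative band.  `validity_report` does the
#' same for device pairs with the Pearson correlation, the paired-t
#' comparison and the correlation band.
#'
#' @param data data frame with columns `parameter`, and either
#'   `measurement_1`/`measurement_2` (reliability) or
#'   `device_a`/`device_b` (validity); one row per subject and parameter.
#' @return a data frame, one row per parameter.
#' @export
reliability_report <- function(data) {
  stopifnot(all(c("parameter", "measurement_1", "measurement_2") %in%
                  names(data)))
  out <- lapply(split(data, data$parameter), function(d) {
    r <- icc_single(d$measurement_1, d$measurement_2)
    data.frame(parameter = d$parameter[1], icc = r$estimate,
               ci_low = r$ci_low, ci_high = r$ci_high, p = r$p,
               band = band_reliability(r$estimate), n = r$n,
               form = r$form)
  })
  out <- do.call(rbind, out[unique(data$parameter)])
  rownames(out) <- NULL
  out
}

#' @rdname reliability_report
#' @export
validity_report <- function(data) {
  stopifnot(all(c("parameter", "device_a", "device_b") %in% names(data)))
  out <- lapply(split(data, data$parameter), function(d) {
    r <- pearson_corr(d$device_a, d$device_b)
    tt <- paired_t(d$device_a, d$device_b)
    data.frame(parameter = d$parameter[1], r = r$r, p = r$p,
               t = tt$t, t_p = tt$p, band = band_correlation(r$r),
               n = r$n)
  })
  out <- do.call(rbind, out[unique(data$parameter)])
  rownames(out) <- NULL
  out
}

#' @rdname reliability_report
#' @param paired reliability input (see `data`).
#' @param device_pairs validity input (see `data`).
#' @export
build_reports <- function(paired = NULL, device_pairs = NULL) {
  out <- list()
  if (!is.null(paired)) out$reliability <- reliability_report(paired)
  if (!is.null(device_pairs)) out$validity <- validity_report(device_pairs)
  # covariate adjustment (age/height/weight/BMI) is deliberately out of
  # scope; flag it so downstream readers know the tables are unadjusted
  attr(out, "adjusted") <- FALSE
  out
}
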