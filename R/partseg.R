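#' SLIC superpixels restricted to a silhouette
#'
#' Localized k-means over (row, col, depth) with grid-seeded centers at
#' step `S = sqrt(area / K)`, assignment within `2S` windows minimizing
#' `D^2 = d_depth^2 + m^2 (d_xy / S)^2` (depth rescaled to `[0, 100]` over
#' the mask), followed by a connectivity pass that reattaches orphan
#' fragments, so the labels partition the mask exactly.  The realized
#' cluster count can be below `K`.
#'
#' @param mask a [extract_silhouette()] result.
#' @param frame the [depth_frame()] the mask came from.
#' @param K target superpixel count.
#' @param m compactness weight.
#' @param max_iter center-update iterations.
#' @return object of class `superpixel_map`: `labels` (0-based integer
#'   matrix, `NA` outside the mask), `K`, `centers` (row, col, mean depth
#'   mm, size), `step`, `objective` (summed squared distance per
#'   iteration).
#' @export
slic_segment <- function(mask, frame, K = 400, m = 20, max_iter = 10) {
  stopifnot(K >= 1)
  if (mask$pixel_count == 0) stop("empty silhouette")
  res <- .slic_cpp(mask$mask, matrix(as.numeric(frame$z), nrow(frame$z)),
                   as.integer(K), m, as.integer(max_iter))
  colnames(res$centers) <- c("row", "col", "depth", "size")
  structure(list(labels = res$labels, K = res$K, centers = res$centers,
                 step = res$step, objective = res$objective,
                 view = mask$view),
            class = "superpixel_map")
}

#' @export
print.superpixel_map <- function(x, ...) {
  cat(sprintf("<superpixel_map> %d superpixels (step %.1f px)\n", x$K, x$step))
  invisible(x)
}

#' Per-superpixel features for body-part classification
#'
#' Six features per superpixel: bounding-box-normalized centroid (u, v in
#' `[0,1]`, v growing downward), mean depth minus the silhouette's median
#' depth (mm), area fraction, elongation (ratio of the second-moment
#' eigenvalues), and the height fraction of the centroid (from the bbox
#' bottom).
#'
#' @param spmap a [slic_segment()] result.
#' @param frame the underlying [depth_frame()].
#' @param mask the [extract_silhouette()] mask.
#' @return matrix `K x 6` with class `superpixel_features`.
#' @export
extract_features <- function(spmap, frame, mask) {
  idx <- which(mask$mask)
  lab <- spmap$labels[idx]
  if (any(is.na(lab))) stop("superpixel map inconsistent with mask")
  rr <- (idx - 1) %% nrow(mask$mask)
  cc <- (idx - 1) %/% nrow(mask$mask)
  z <- as.numeric(frame$z[idx])
  g <- lab + 1L
  n <- tabulate(g, spmap$K)
  sums <- function(v) rowsum(v, g)[, 1]
  mr <- sums(rr) / n; mc <- sums(cc) / n
  vr <- sums(rr^2) / n - mr^2
  vc <- sums(cc^2) / n - mc^2
  vrc <- sums(rr * cc) / n - mr * mc
  # eigenvalues of the 2x2 second-moment matrix; 1/12 px^2 quantization floor
  tr2 <- (vr + vc) / 2
  disc <- sqrt(pmax(tr2^2 - (vr * vc - vrc^2), 0))
  l1 <- tr2 + disc + 1 / 12
  l2 <- pmax(tr2 - disc, 0) + 1 / 12
  r0 <- min(rr); r1 <- max(rr); c0 <- min(cc); c1 <- max(cc)
  u_norm <- (mc - c0) / max(c1 - c0, 1)
  v_norm <- (mr - r0) / max(r1 - r0, 1)
  out <- cbind(u_norm = u_norm, v_norm = v_norm,
               depth_rel = sums(z) / n - median(z),
               area_frac = n / length(idx),
               elongation = l1 / l2,
               height_frac = 1 - v_norm)
  class(out) <- c("superpixel_features", class(out))
  out
}

#' Majority ground-truth part label per superpixel
#'
#' @param spmap a [slic_segment()] result.
#' @param part_mask integer matrix of true per-pixel part ids (0 outside
#'   the body), as attached by [render_session()].
#' @param min_purity superpixels whose majority label covers less than this
#'   fraction are returned as `NA` (dropped from training).
#' @return character vector of part-class names, length `spmap$K`.
#' @export
majority_part_labels <- function(spmap, part_mask, min_purity = 0.6) {
  idx <- which(!is.na(spmap$labels))
  lab <- spmap$labels[idx] + 1L
  part <- part_mask[idx]
  cls <- part_classes()
  out <- rep(NA_character_, spmap$K)
  tab <- table(factor(lab, levels = seq_len(spmap$K)),
               factor(part, levels = 0:length(cls)))
  best <- max.col(tab, ties.method = "first")
  purity <- tab[cbind(seq_len(spmap$K), best)] / pmax(rowSums(tab), 1)
  id <- best - 2L   # column 1 is background id 0
  ok <- purity >= min_purity & id >= 0L
  out[ok] <- cls[id[ok] + 1L]
  out
}

#' Train a maximum-margin linear body-part classifier
#'
#' Soft-margin linear classifier (per-class weight vector and bias) fitted
#' by seeded mini-batch stochastic subgradient descent on the
#' L2-regularized multiclass hinge loss (Pegasos-style step sizes),
#' returning the averaged iterate.  The multiclass hinge couples the
#' classes through the argmax, which is essential here: several part
#' regions (pelvis, neck) are slabs sandwiched between neighbours, so they
#' are representable by argmax-of-linear scores but not separable by any
#' independent per-class binary classifier.  Classes are re-weighted by
#' (capped) inverse frequency so small parts are not drowned out.
#' Features are standardized internally; the scaling is stored with the
#' weights.
#'
#' @param x feature matrix (rows = samples).
#' @param y character or factor of class labels (`NA` rows are dropped).
#' @param lambda L2 regularization strength.
#' @param epochs passes over the data.
#' @param seed RNG seed; identical seeds give identical weights.
#' @param batch mini-batch size.
#' @param classes class universe (defaults to the levels present).
#' @return object of class `margin_classifier`.
#' @export
train_parts <- function(x, y, lambda = 1e-3, epochs = 30, seed = 1,
                        batch = 64, classes = NULL) {
  keep <- !is.na(y)
  x <- as.matrix(x)[keep, , drop = FALSE]
  y <- as.character(y)[keep]
  if (is.null(classes)) classes <- sort(unique(y))
  if (length(unique(y)) < 2) stop("degenerate training set")
  n <- nrow(x); d <- ncol(x); C <- length(classes)
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd); scl[scl < 1e-9] <- 1
  xs <- cbind(sweep(sweep(x, 2, ctr), 2, scl, "/"), 1)  # bias column
  yid <- match(y, classes)
  # inverse-frequency sample weights, capped so rare classes cannot
  # dominate the subgradient either
  nc <- pmax(tabulate(yid, C), 1)
  wsamp <- pmin(n / (C * nc), 8)[yid]

  W <- matrix(0, C, d + 1)
  Wsum <- W
  with_seed(seed, {
    t <- 0
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = batch)) {
        t <- t + 1
        ii <- ord[start:min(start + batch - 1, n)]
        B <- length(ii)
        eta <- 1 / (lambda * (t + 1 / lambda))
        sc <- xs[ii, , drop = FALSE] %*% t(W)        # B x C
        true_sc <- sc[cbind(seq_len(B), yid[ii])]
        sc[cbind(seq_len(B), yid[ii])] <- -Inf
        comp <- max.col(sc, ties.method = "first")   # hardest rival class
        viol <- 1 + sc[cbind(seq_len(B), comp)] - true_sc > 0
        grad <- matrix(0, C, d + 1)
        if (any(viol)) {
          vv <- which(viol)
          xv <- xs[ii[vv], , drop = FALSE] * wsamp[ii[vv]]
          up <- rowsum(xv, yid[ii[vv]])
          grad[as.integer(rownames(up)), ] <- up
          dn <- rowsum(xv, comp[vv])
          grad[as.integer(rownames(dn)), ] <-
            grad[as.integer(rownames(dn)), , drop = FALSE] - dn
          grad <- grad / B
        }
        W <- (1 - eta * lambda) * W + eta * grad
        Wsum <- Wsum + W
      }
    }
    W <- Wsum / t
  })
  structure(list(weights = W[, seq_len(d), drop = FALSE],
                 bias = W[, d + 1],
                 classes = classes, center = ctr, scale = scl,
                 lambda = lambda, epochs = epochs, seed = seed,
                 features = colnames(x)),
            class = "margin_classifier")
}

#' @export
print.margin_classifier <- function(x, ...) {
  cat(sprintf("<margin_classifier> %d classes x %d features (lambda %g, %d epochs, seed %d)\n",
              length(x$classes), ncol(x$weights), x$lambda, x$epochs, x$seed))
  invisible(x)
}

#' Regularized hinge objective of a classifier on a data set
#' @inheritParams train_parts
#' @param clf a [train_parts()] result.
#' @return scalar objective (summed over the one-vs-rest problems).
#' @export
hinge_objective <- function(clf, x, y) {
  keep <- !is.na(y)
  x <- as.matrix(x)[keep, , drop = FALSE]
  y <- as.character(y)[keep]
  xs <- sweep(sweep(x, 2, clf$center), 2, clf$scale, "/")
  sc <- xs %*% t(clf$weights) + rep(1, nrow(xs)) %o% clf$bias
  n <- nrow(xs); C <- length(clf$classes)
  yid <- match(y, clf$classes)
  nc <- pmax(tabulate(yid, C), 1)
  wsamp <- pmin(n / (C * nc), 8)[yid]
  true_sc <- sc[cbind(seq_len(n), yid)]
  sc[cbind(seq_len(n), yid)] <- -Inf
  hin <- pmax(0, 1 + apply(sc, 1, max) - true_sc)
  sum(clf$lambda / 2 * rowSums(cbind(clf$weights, clf$bias)^2)) +
    mean(hin * wsamp)
}

#' Predict body parts for superpixels
#'
#' Per-superpixel argmax of the one-vs-rest scores; ties break toward the
#' lowest class index.
#'
#' @param clf a [train_parts()] result.
#' @param features a [extract_features()] matrix.
#' @return object of class `part_labeling`: character vector `class` of
#'   length `K` plus the score matrix.
#' @export
predict_parts <- function(clf, features) {
  x <- as.matrix(features)
  if (ncol(x) != ncol(clf$weights)) stop("feature/classifier mismatch")
  xs <- sweep(sweep(x, 2, clf$center), 2, clf$scale, "/")
  sc <- xs %*% t(clf$weights) + rep(1, nrow(xs)) %o% clf$bias
  colnames(sc) <- clf$classes
  pick <- max.col(sc, ties.method = "first")
  structure(list(class = clf$classes[pick], scores = sc),
            class = "part_labeling")
}

#' Persist / load a part classifier (or per-view bundle) as JSON
#'
#' @param clf a `margin_classifier` or a named list of them (one per view).
#' @param path JSON path.
#' @export
save_classifier <- function(clf, path) {
  ser <- function(cl) list(weights = cl$weights, bias = cl$bias,
                           classes = cl$classes, center = cl$center,
                           scale = cl$scale, lambda = cl$lambda,
                           epochs = cl$epochs, seed = cl$seed,
                           features = cl$features)
  obj <- if (inherits(clf, "margin_classifier")) ser(clf) else lapply(clf, ser)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  des <- function(o) {
    w <- o$weights
    if (is.list(w)) w <- do.call(rbind, w)
    structure(list(weights = as.matrix(w), bias = as.numeric(o$bias),
                   classes = as.character(o$classes),
                   center = as.numeric(o$center), scale = as.numeric(o$scale),
                   lambda = o$lambda, epochs = o$epochs, seed = o$seed,
                   features = as.character(o$features)),
              class = "margin_classifier")
  }
  o <- jsonlite::fromJSON(path)
  if (!is.null(o$weights)) des(o) else lapply(o, des)
}
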