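square_mask <- function(n = 80, d = 2500L) {
  z <- matrix(4000L, n + 20, n + 20)
  z[11:(10 + n), 11:(10 + n)] <- d
  fr <- depth_frame(z, "front")
  bg <- depth_frame(matrix(4000L, n + 20, n + 20), "front")
  list(frame = fr,
       sil = extract_silhouette(fr, bg, z_band = c(1900, 3100),
                                min_area = 10))
}

test_that("SLIC partitions a uniform square into near-equal superpixels", {
  sq <- square_mask(80)
  sp <- slic_segment(sq$sil, sq$frame, K = 4, m = 20, max_iter = 10)
  expect_equal(sp$K, 4)
  areas <- sp$centers[, "size"]
  expect_true(all(abs(areas - 1600) / 1600 <= 0.2))
})

test_that("K = 1 yields a single superpixel equal to the mask", {
  sq <- square_mask(40)
  sp <- slic_segment(sq$sil, sq$frame, K = 1)
  expect_equal(sp$K, 1)
  expect_true(all(sp$labels[sq$sil$mask] == 0))
})

test_that("labels partition the mask exactly and connectedly", {
  sess <- pk_session()
  for (v in c("front", "back")) {
    vd <- pk_view(sess, v)
    lab <- vd$sp$labels
    expect_true(all(!is.na(lab[vd$sil$mask])))
    expect_true(all(is.na(lab[!vd$sil$mask])))
    expect_true(all(lab[vd$sil$mask] >= 0 & lab[vd$sil$mask] < vd$sp$K))
    expect_equal(sum(vd$sp$centers[, "size"]), vd$sil$pixel_count)
    # every superpixel is 4-connected
    for (j in sample(0:(vd$sp$K - 1), 25)) {
      cc <- posturekit:::.cc_label(!is.na(lab) & lab == j)
      expect_equal(length(cc$sizes), 1)
    }
  }
})

test_that("the SLIC objective is non-increasing over iterations", {
  sess <- pk_session()
  vd <- pk_view(sess, "front")
  expect_true(all(diff(vd$sp$objective) <= 1e-6))
})

test_that("superpixel features satisfy their invariants", {
  sq <- square_mask(60)
  sp <- slic_segment(sq$sil, sq$frame, K = 1)
  feat <- extract_features(sp, sq$frame, sq$sil)
  expect_equal(unname(feat[1, "u_norm"]), 0.5, tolerance = 1e-9)
  expect_equal(unname(feat[1, "depth_rel"]), 0)   # constant depth
  expect_equal(unname(feat[1, "area_frac"]), 1)

  sess <- pk_session()
  vd <- pk_view(sess, "front")
  expect_equal(sum(vd$feat[, "area_frac"]), 1, tolerance = 1e-9)
  expect_true(all(vd$feat[, c("u_norm", "v_norm")] >= 0 &
                    vd$feat[, c("u_norm", "v_norm")] <= 1))
  expect_true(all(vd$feat[, "elongation"] >= 1 - 1e-9))
})

test_that("training separates a linearly separable toy problem", {
  set.seed(7)
  x <- rbind(cbind(rnorm(100, -4), rnorm(100, 0)),
             cbind(rnorm(100, 4), rnorm(100, 0)))
  y <- rep(c("a", "b"), each = 100)
  clf <- train_parts(x, y, lambda = 1e-3, epochs = 30, seed = 1)
  expect_equal(mean(predict_parts(clf, x)$class == y), 1)

  # training exemplar of a margin-separated class maps to that class
  expect_equal(predict_parts(clf, x[1, , drop = FALSE])$class, "a")

  # reproducibility
  clf2 <- train_parts(x, y, lambda = 1e-3, epochs = 30, seed = 1)
  expect_identical(clf$weights, clf2$weights)
  clf3 <- train_parts(x, y, lambda = 1e-3, epochs = 30, seed = 2)
  expect_false(identical(clf$weights, clf3$weights))

  # longer training does not worsen the regularized objective
  half <- train_parts(x, y, lambda = 1e-3, epochs = 15, seed = 1)
  expect_lte(hinge_objective(clf, x, y), hinge_objective(half, x, y) + 1e-6)

  expect_error(train_parts(x, rep("a", 200)), "degenerate training set")
})

test_that("prediction follows the argmax with low-index tie-breaking", {
  clf <- structure(list(weights = matrix(0, 3, 2), bias = c(0, 0, 0),
                        classes = c("a", "b", "c"), center = c(0, 0),
                        scale = c(1, 1), lambda = 1e-3, epochs = 1,
                        seed = 1, features = c("f1", "f2")),
                   class = "margin_classifier")
  out <- predict_parts(clf, matrix(rnorm(10), 5, 2))
  expect_true(all(out$class == "a"))
  expect_error(predict_parts(clf, matrix(0, 2, 3)),
               "feature/classifier mismatch")
})

test_that("classifiers survive a JSON round trip", {
  clf <- pk_classifier()
  path <- tempfile(fileext = ".json")
  save_classifier(clf, path)
  rd <- load_classifier(path)
  expect_equal(rd$front$weights, clf$front$weights, ignore_attr = TRUE)
  expect_equal(rd$back$bias, clf$back$bias, ignore_attr = TRUE)
  expect_identical(rd$side$classes, clf$side$classes)
  sess <- pk_session()
  vd <- pk_view(sess, "front")
  expect_identical(predict_parts(rd$front, vd$feat)$class, vd$lab$class)
})

test_that("majority labels respect the purity threshold", {
  sess <- pk_session()
  vd <- pk_view(sess, "front")
  lab0 <- majority_part_labels(vd$sp, sess$truth$part_masks$front,
                               min_purity = 0)
  lab9 <- majority_part_labels(vd$sp, sess$truth$part_masks$front,
                               min_purity = 0.9)
  expect_true(all(is.na(lab0) | lab0 %in% part_classes()))
  expect_gte(sum(is.na(lab9)), sum(is.na(lab0)))
  expect_true(all(lab9[!is.na(lab9)] == lab0[!is.na(lab9)]))
})

test_that("mirroring a front frame swaps left/right predictions", {
  sess <- pk_session()
  clf <- pk_classifier()
  vd <- pk_view(sess, "front")
  truth <- majority_part_labels(vd$sp, sess$truth$part_masks$front,
                                min_purity = 0)
  ok <- !is.na(truth)
  acc <- mean(vd$lab$class[ok] == truth[ok])

  flip <- function(m) m[, ncol(m):1]
  fr_m <- depth_frame(flip(sess$frames$front[[1]]$z), "front")
  bg_m <- depth_frame(flip(sess$background$front$z), "front")
  sil_m <- extract_silhouette(fr_m, bg_m, camera = sess$camera)
  sp_m <- slic_segment(sil_m, fr_m)
  lab_m <- predict_parts(clf$front, extract_features(sp_m, fr_m, sil_m))
  swap <- function(cls) {
    l <- grepl("_L$", cls); r <- grepl("_R$", cls)
    cls[l] <- sub("_L$", "_R", cls[l]); cls[r] <- sub("_R$", "_L", cls[r])
    cls
  }
  truth_m <- swap(majority_part_labels(sp_m, flip(sess$truth$part_masks$front),
                                       min_purity = 0))
  ok_m <- !is.na(truth_m)
  acc_m <- mean(lab_m$class[ok_m] == truth_m[ok_m])
  expect_lt(abs(acc - acc_m), 0.06)
  expect_gt(acc_m, 0.85)
})
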