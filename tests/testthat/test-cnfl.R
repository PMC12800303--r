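pitch <- default_pixel_pitch_um()

test_that("skeletonization thins bars to single paths and preserves topology", {
  tr <- nerve_tracing(list(cbind(c(10, 90), c(50, 50))), c(100L, 100L))
  sk <- skeletonize(rasterize_nerve_mask(tr, 4))
  expect_equal(length(unique(which(sk == 1, arr.ind = TRUE)[, 1])), 1)
  expect_true(all(sk <= rasterize_nerve_mask(tr, 4)$data))

  expect_equal(sum(skeletonize(matrix(0L, 32, 32))), 0)

  two <- nerve_tracing(list(cbind(c(5, 60), c(20, 20)),
                            cbind(c(5, 60), c(70, 70))), c(100L, 100L))
  sk2 <- skeletonize(rasterize_nerve_mask(two, 4))
  expect_equal(max(label_components8(sk2)), 2)
  expect_equal(max(label_components8(skeletonize(
    rasterize_nerve_mask(two, 4)$data, prune_px = 0))), 2)
})

test_that("skeleton length follows the weighted link-count closed forms", {
  sk <- matrix(0L, 400, 400)
  sk[100, 1:385] <- 1L
  expect_equal(skeleton_length_mm(sk, pitch), 384 * pitch / 1000)
  expect_equal(skeleton_length_mm(sk, pitch), 0.4)

  diagk <- matrix(0L, 60, 60)
  for (i in 1:50) diagk[i, i] <- 1L
  expect_equal(skeleton_length_mm(diagk, pitch), 49 * sqrt(2) * pitch / 1000)

  expect_equal(skeleton_length_mm(matrix(0L, 10, 10)), 0)
  # an L-corner's diagonal chord is not double-counted
  ell <- matrix(0L, 5, 5)
  ell[2, 2] <- ell[2, 3] <- ell[3, 3] <- 1L
  expect_equal(skeleton_length_mm(ell, pitch), 2 * pitch / 1000)
})

test_that("skeleton length recovers analytic arc length on low-curvature splines", {
  # the per-curve guarantee holds for near-vertical, gently curved fibres
  # (tangent within ~15 deg of vertical) of at least 100 px arc length:
  # thinning retracts each butt-capped end by about half the stroke width,
  # a fixed cost that dominates only for very short fragments
  p <- synth_params(image_shape = c(256L, 256L), nerve_angle_sd_deg = 5,
                    nerve_wiggle_amp_deg = c(1, 5))
  errs <- vapply(1:20, function(i) {
    smp <- generate_sample(p, seed = 600 + i, n_nerves = 1, n_with = 0,
                           n_without = 0)
    len_px <- smp$true_nerve_length_mm * 1000 / p$pixel_pitch_um
    if (len_px < 100) return(0)      # below the stated length bound
    truth <- smp$true_nerve_length_mm
    est <- skeleton_length_mm(skeletonize(rasterize_nerve_mask(smp$tracing)),
                              p$pixel_pitch_um)
    abs(est - truth) / truth
  }, numeric(1))
  expect_lt(max(errs), 0.05)
})

test_that("per-image estimates compose and add across disjoint nerves", {
  expect_equal(cnfl_image(matrix(0L, 64, 64))$length_mm, 0)
  one <- rasterize_nerve_mask(vertical_tracing(20, c(64L, 64L)))
  three <- rasterize_nerve_mask(nerve_tracing(
    list(cbind(c(12, 12), c(0, 63)), cbind(c(30, 30), c(0, 63)),
         cbind(c(48, 48), c(0, 63))), c(64L, 64L)))
  l1 <- cnfl_image(one)$length_mm
  l3 <- cnfl_image(three)$length_mm
  expect_equal(l3, 3 * l1, tolerance = 1e-12)

  full <- rasterize_nerve_mask(nerve_tracing(
    list(cbind(c(30, 30), c(0, 383))), c(384L, 384L)))
  # thinning retracts the butt-capped stroke ends by about half the width
  expect_equal(cnfl_image(full)$length_mm, 0.4, tolerance = 0.02)
})

test_that("participant CNFL density is the exact closed form", {
  agg <- cnfl_participant(rep(2.768, 10))
  expect_equal(agg$avg_length_mm, 2.768)
  expect_equal(agg$cnfl_density, 17.3, tolerance = 1e-12)
  expect_equal(cnfl_participant(rep(0, 5))$cnfl_density, 0)
  expect_equal(cnfl_participant(0.16, area_mm2 = 0.16)$cnfl_density, 1.0)
  expect_error(cnfl_participant(numeric(0)), "at least one")
  expect_error(cnfl_participant(1, area_mm2 = 0), "area")

  # rational-arithmetic oracle: lengths k/1000 mm, area a/b mm^2
  set.seed(77)
  for (i in 1:25) {
    num <- sample(1:5000, sample(1:12, 1), replace = TRUE)
    a <- sample(1:32, 1); b <- sample(1:200, 1)
    agg <- cnfl_participant(num / 1000, area_mm2 = a / b)
    exact <- (sum(num) * b) / (1000 * length(num) * a)
    expect_equal(agg$cnfl_density, exact, tolerance = 1e-12)
  }
})

test_that("the default image area follows from the imaging geometry", {
  # exact in real arithmetic; double precision carries 400/384 to ~1e-16
  expect_equal(image_area_mm2(), 0.16, tolerance = 1e-12)
  expect_lt(abs(default_pixel_pitch_um() - 400 / 384), 1e-12)
})

test_that("estimator selection prefers lower MAPE, then lower MAE, then simplicity", {
  truth <- c(2.5, 3.0, 2.8, 3.1)
  sel <- select_estimator(truth * 1.0404, truth * 1.0343, truth)
  expect_equal(sel$chosen, "regression")
  expect_equal(sel$report$mape, c(4.04, 3.43), tolerance = 1e-9)

  tie <- select_estimator(truth * 1.02, truth * 0.98, truth)
  expect_equal(tie$chosen, "algorithmic")

  exact <- select_estimator(truth * 1.05, truth, truth)
  expect_equal(exact$chosen, "regression")
  expect_error(select_estimator(1:3, 1:3, 1:4), "equal length")
})

test_that("the length regressor fits constants, overfits small sets, stays non-negative", {
  p <- tiny_params(c(32L, 32L))
  samples <- lapply(1:5, function(i) generate_sample(p, seed = 700 + i))
  imgs <- lapply(samples, `[[`, "image")
  lens <- vapply(samples, `[[`, numeric(1), "true_nerve_length_mm")

  cfg <- length_regressor_config(depth = 2L, base_channels = 4L,
                                 epochs = 150L, learning_rate = 5e-3,
                                 seed = 4L)
  const <- train_length_regressor(build_length_regressor(cfg), imgs,
                                  rep(0.25, 5))
  preds <- vapply(imgs, function(im)
    predict_length(const, im)$length_mm, numeric(1))
  expect_lt(max(abs(preds - 0.25)), 0.05)
  expect_true(all(preds >= 0))

  cfg2 <- length_regressor_config(depth = 2L, base_channels = 8L,
                                  epochs = 400L, learning_rate = 3e-3,
                                  seed = 4L)
  fit <- train_length_regressor(build_length_regressor(cfg2), imgs, lens)
  fit_mae <- mae(vapply(imgs, function(im)
    predict_length(fit, im)$length_mm, numeric(1)), lens)
  expect_lte(fit_mae, 0.02)
  expect_error(train_length_regressor(build_length_regressor(cfg), list(),
                                      numeric(0)), "empty")
})
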