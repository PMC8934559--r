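test_that("CAM respects the head-weight contract", {
  fx <- trained_gap_cnn()
  m <- fx$model
  img <- fx$ds$images[[1]]
  cam <- compute_cam(m, img, "mirror")
  expect_equal(dim(unclass(cam)), c(64L, 64L))
  expect_true(all(is.finite(cam)))
  # zero head weights give an all-zero map
  m0 <- m; m0$head$w2[] <- 0
  expect_true(all(unclass(compute_cam(m0, img, "mirror")) == 0))
  # single nonzero weight: map is that feature map, upsampled and scaled
  m1 <- m; m1$head$w2[] <- 0; m1$head$w2[2, 2] <- 1.5
  cam1 <- compute_cam(m1, img, "mirror")
  acts <- cnn_activations(m, array(img$pixels, c(64, 64, 3, 1)))
  fmap <- mirrorglass:::maxpool_forward(
    aperm(acts$relu2, c(1, 2, 4, 3)), m$spec$pool_size)$y[, , 1, 2]
  expect_equal(unclass(cam1),
               1.5 * mirrorglass:::bilinear_upsample(fmap, 64L),
               tolerance = 1e-10)
  # linearity in the head weights (superposition)
  wa <- withr::with_seed(1L, rnorm(length(m$head$w2[, 2])))
  wb <- withr::with_seed(2L, rnorm(length(m$head$w2[, 2])))
  ma <- m; ma$head$w2[, 2] <- wa
  mb <- m; mb$head$w2[, 2] <- wb
  mab <- m; mab$head$w2[, 2] <- wa + wb
  expect_equal(unclass(compute_cam(ma, img, "mirror")) +
                 unclass(compute_cam(mb, img, "mirror")),
               unclass(compute_cam(mab, img, "mirror")), tolerance = 1e-10)
  # flatten-head models are rejected
  flat <- build_cnn(cnn_spec(depth = 1L, gap_head = FALSE), seed = 1L)
  expect_error(compute_cam(flat, img, "mirror"), "gap_head")
})

test_that("mean CAM differences are discriminant maps with the stated identities", {
  fx <- trained_gap_cnn()
  two <- fx$ds$images[c(
    which(fx$ds$manifest$class_label == "mirror")[1],
    which(fx$ds$manifest$class_label == "glass")[1])]
  # single image per class: difference equals the per-image discriminant
  # difference (w_mirror - w_glass applied to each image's feature maps)
  dm <- fx$model
  dvec <- dm$head$w2[, 2] - dm$head$w2[, 1]
  dm$head$w2 <- cbind(-dvec, dvec)
  d <- class_mean_cam_difference(fx$model, two)
  expect_equal(d$difference,
               unclass(compute_cam(dm, two[[1]], "mirror")) -
                 unclass(compute_cam(dm, two[[2]], "mirror")),
               tolerance = 1e-12)
  # identical image lists for both classes give an exactly zero difference
  same <- list(two[[1]], two[[2]])
  d0 <- class_mean_cam_difference(fx$model, list(two[[1]], two[[2]],
                                                 two[[1]], two[[2]]),
                                  labels = c("mirror", "mirror",
                                             "glass", "glass"))
  expect_equal(d0$difference, matrix(0, 64, 64), tolerance = 1e-12,
               ignore_attr = TRUE)
  # streaming mean equals recomputed mean over a larger set
  imgs <- fx$ds$images[c(1:5, 41:45)]
  dd <- class_mean_cam_difference(fx$model, imgs)
  y <- vapply(imgs, function(im) im$spec$class_label, character(1))
  per <- lapply(imgs, function(im) unclass(compute_cam(dm, im, "mirror")))
  mm <- Reduce(`+`, per[y == "mirror"]) / sum(y == "mirror")
  mg <- Reduce(`+`, per[y == "glass"]) / sum(y == "glass")
  expect_equal(dd$difference, mm - mg, tolerance = 1e-12)
})

test_that("vertical profiles are row means with hand-checked values", {
  expect_equal(vertical_profile(matrix(0.3, 64, 64)), rep(0.3, 64))
  ramp <- matrix(seq_len(64), 64, 64)
  expect_true(all(diff(vertical_profile(ramp)) > 0))
  toy <- matrix(c(1, 3, 2, 4), 2, 2)
  expect_equal(vertical_profile(toy), c(1.5, 3.5))
  expect_error(vertical_profile(1:5), "2-D")
  expect_equal(profile_correlation(1:10, 1:10), 1.0)
  expect_equal(profile_correlation(1:10, -(1:10)), -1.0)
})

test_that("CAM difference peaks above the midline and tracks pixel intensity", {
  # gradient-only cue: the planted regularity is strictly vertical
  hits <- 0L
  for (seed in c(21L, 22L, 23L)) {
    fx <- trained_gap_cnn(seed)
    d <- class_mean_cam_difference(fx$model, fx$ds$images)
    p <- class_mean_pixel_difference(fx$ds$images)
    camp <- vertical_profile(d$difference)
    pixp <- vertical_profile(p$difference)
    expect_lt(which.max(camp), 32L)
    expect_gt(profile_correlation(camp, pixp), 0.8)
  }
})

test_that("noise robustness saturates and the clean end matches the model", {
  fx <- trained_gap_cnn()
  ratings <- pmin(pmax(fx$ds$manifest$a, 0), 1)
  curve <- noise_robustness_curve(fx$model, fx$x, ratings,
                                  sigmas = c(0, 1e-2, 1e-1, 1, 100),
                                  n_reps = 3L, seed = 2L)
  clean_r <- cor(predict_cnn(fx$model, fx$x), ratings)
  expect_equal(curve$r[curve$sigma == 0], clean_r, tolerance = 1e-10)
  expect_lt(abs(curve$r[curve$sigma == 100]), 0.1)
  # nonincreasing within 2 MC sd
  slack <- 2 * pmax(curve$mc_sd[-1], curve$mc_sd[-nrow(curve)])
  expect_true(all(diff(curve$r) <= slack + 1e-8))
})

test_that("inversion flips hurt gradient-cued models and respect symmetry", {
  for (seed in c(21L, 22L, 23L)) {
    fx <- trained_flat_cnn(seed)
    test_ds <- generate_dataset(20L, strong_mix(), master_seed = seed + 500L,
                                gains = gradient_gains())
    tx <- stack_images(test_ds$images)
    inv <- inversion_test(fx$model, tx, test_ds$manifest$class_label)
    expect_gt(inv$delta, 0)
    # double flip recovers upright accuracy exactly
    inv2 <- inversion_test(fx$model, flip_vertical(flip_vertical(tx)),
                           test_ds$manifest$class_label)
    expect_equal(inv2$accuracy_upright, inv$accuracy_upright)
  }
})
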