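# Augmentations, the branch-switching sampler, the masked loss, and a
# short optimization smoke run.

test_that("masked MAE pools both axes over valid points only", {
  Yp <- rbind(c(10, 10), c(5, 5))
  Yt <- hp_points(rbind(c(10, 10), c(5, 5)))
  expect_equal(masked_mae_loss(Yp, Yt), 0)

  Yp2 <- rbind(c(13, 6), c(99, 99))
  Yt2 <- hp_points(rbind(c(10, 10), c(0, 0)), valid = c(TRUE, FALSE))
  expect_equal(masked_mae_loss(Yp2, Yt2), 3.5)

  # perturbing sentinel rows leaves the loss unchanged
  Yp3 <- Yp2
  Yp3[2, ] <- c(-50, 7)
  expect_equal(masked_mae_loss(Yp3, Yt2), 3.5)

  expect_error(masked_mae_loss(Yp2, Yt2, valid = c(TRUE, TRUE)), "disagree")
  expect_warning(
    expect_equal(masked_mae_loss(Yp2, hp_points(matrix(0, 2, 2),
                                                valid = c(FALSE, FALSE))), 0),
    "no valid")
})

test_that("loss is invariant to a consistent permutation of the points", {
  set.seed(5)
  Yp <- matrix(runif(20, 0, 100), 10, 2)
  Yt <- matrix(runif(20, 0, 100), 10, 2)
  l1 <- masked_mae_loss(Yp, hp_points(Yt))
  perm <- sample(10)
  l2 <- masked_mae_loss(Yp[perm, ], hp_points(Yt[perm, ]))
  expect_equal(l1, l2)
})

test_that("zero-magnitude TPS augmentation is the identity", {
  ph <- small_phantom()
  out <- random_tps_augment(ph$moving, ph$gt_moving,
                            aug_params(tps_max_dev = 0), seed = 1)
  expect_lt(max(abs(out$image$pixels - ph$moving$pixels)), 1e-6)
  expect_equal(out$points$coords, ph$gt_moving$coords)
})

test_that("TPS augmentation tracks a delta marker and caps displacements", {
  S <- 128
  pt <- c(70.5, 48.5)
  img <- matrix(0, S, S)
  img[71, 49] <- 1  # pixel whose center is the tracked point
  out <- random_tps_augment(hp_image(img, "histology"), hp_points(rbind(pt)),
                            aug_params(tps_max_dev = 12), seed = 44)
  peak <- which(out$image$pixels == max(out$image$pixels), arr.ind = TRUE)
  peak_center <- c(peak[1, 1] - 0.5, peak[1, 2] - 0.5)
  expect_lt(sqrt(sum((peak_center - out$points$coords[1, ])^2)), 1)

  # control displacements: per-axis never above the cap
  for (s in 1:5) {
    a <- random_tps_augment(small_phantom()$moving, hp_points(NULL),
                            aug_params(tps_max_dev = 16), seed = s)
    gp <- a$transform$source_points
    disp <- hpreg:::tps_eval(a$transform, gp) - gp
    expect_lte(max(abs(disp)), 16)
    expect_lte(max(sqrt(rowSums(disp^2))), 16 * sqrt(2))
  }
})

test_that("rotation augmentation follows the stated convention and is an
           isometry about the center", {
  S <- 512
  img <- hp_image(matrix(0.5, S, S), "mr")
  pts <- hp_points(rbind(c(256, 356)))
  out <- random_rotation_augment(img, pts, theta = 90)
  expect_equal(out$points$coords[1, ], c(356, 256), tolerance = 1e-9)

  # matrix oracle
  th <- 37 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2, byrow = TRUE)
  p <- c(300, 140)
  o2 <- random_rotation_augment(img, hp_points(rbind(p)), theta = 37)
  expect_equal(o2$points$coords[1, ],
               drop(R %*% (p - 256)) + 256, tolerance = 1e-9)

  o0 <- random_rotation_augment(img, pts, theta = 0)
  expect_identical(o0$image$pixels, img$pixels)
  expect_equal(o0$points$coords, pts$coords)

  set.seed(2)
  q <- matrix(runif(40, 50, 450), 20, 2)
  o3 <- random_rotation_augment(img, hp_points(q), theta = -20)
  d_before <- sqrt(rowSums((q - 256)^2))
  d_after <- sqrt(rowSums((o3$points$coords - 256)^2))
  expect_lt(max(abs(d_before - d_after)), 1e-9)
})

test_that("ground truth follows composed augmentations within half a pixel", {
  ph <- small_phantom()
  prm <- aug_params(tps_max_dev = 10)
  tps <- random_tps_augment(ph$moving, ph$gt_moving, prm, seed = 3)
  rot <- random_rotation_augment(tps$image, tps$points, prm, seed = 4)
  # marker image: single bright pixels at the original ground truth
  marker <- matrix(0, 128, 128)
  cc <- round(ph$gt_moving$coords - 0.5) + 1
  marker[cc] <- 1
  mt <- random_tps_augment(hp_image(marker, "histology"), ph$gt_moving, prm,
                           seed = 3)
  mr <- random_rotation_augment(mt$image, mt$points, prm,
                                theta = rot$theta)
  # each mapped point must sit within 0.5 px (+ marker quantization) of a
  # bright blob in the doubly-warped marker image
  px <- mr$image$pixels
  for (i in seq_len(nrow(rot$points$coords))) {
    p <- rot$points$coords[i, ]
    if (any(p < 3) || any(p > 125)) next
    win <- px[max(1, round(p[1]) - 2):min(128, round(p[1]) + 3),
              max(1, round(p[2]) - 2):min(128, round(p[2]) + 3)]
    expect_gt(max(win), 0.15)
  }
})

test_that("the sampler honors the same-modality fraction and is seeded", {
  ds <- list(phantom_to_slide_fixture())
  ex0 <- sample_training_example(ds, same_modality_fraction = 0,
                                 L = 32, seed = 1)
  expect_equal(ex0$moving_modality, "histology")
  expect_equal(ex0$fixed_modality, "mr")

  draws <- vapply(1:400, function(i) {
    ex <- sample_training_example(ds, same_modality_fraction = 1, L = 32,
                                  seed = i, augment = FALSE)
    ex$moving_modality
  }, character(1))
  expect_true(all(vapply(1:400, function(i) {
    ex <- sample_training_example(ds, same_modality_fraction = 1, L = 32,
                                  seed = i, augment = FALSE)
    identical(ex$moving_modality, ex$fixed_modality)
  }, logical(1))))
  # histology vs MR choice is an unbiased coin (3 sigma at n = 400)
  nh <- sum(draws == "histology")
  expect_lt(abs(nh - 200), 3 * sqrt(400 * 0.25))

  a <- sample_training_example(ds, 0.5, L = 32, seed = 99)
  b <- sample_training_example(ds, 0.5, L = 32, seed = 99)
  expect_identical(a$X$coords, b$X$coords)
  expect_identical(a$fixed$pixels, b$fixed$pixels)

  expect_error(sample_training_example(list()), "empty")
})

test_that("a short seeded run reduces the loss and epochs = 0 is a no-op", {
  cfg <- model_config(image_size = 64, patch_size = 8, embed_dim = 16,
                      n_blocks = 2, n_heads = 2, L = 16)
  ds <- list(phantom_to_slide_fixture(size = 64))
  res0 <- train(ds, cfg, epochs = 0, seed = 3)
  init <- init_model(cfg, seed = derive_seed(3, 1L))
  expect_identical(res0$model$weights, init$weights)

  res <- train(ds, cfg, epochs = 200, params = aug_params(tps_max_dev = 6),
               lr = 2e-3, batch_size = 4, same_modality_fraction = 1,
               seed = 3)
  early <- mean(res$step_losses[1:5])
  late <- mean(tail(res$step_losses, 10))
  expect_lt(late, 0.5 * early)

  res_b <- train(ds, cfg, epochs = 2, params = aug_params(tps_max_dev = 6),
                 lr = 2e-3, batch_size = 4, same_modality_fraction = 1,
                 seed = 3)
  expect_equal(res_b$step_losses, res$step_losses[1:length(res_b$step_losses)],
               tolerance = 1e-10)
})
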