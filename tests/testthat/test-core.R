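# Image normalization, foreground box, center-zoom, and point plumbing.

test_that("normalize_image rescales to [0,1], handles RGB and degenerate input", {
  raw <- matrix(as.numeric(0:255), 16, 16)
  img <- normalize_image(raw, "histology")
  expect_equal(img$pixels, raw / 255)

  expect_equal(normalize_image(matrix(3.7, 8, 8), "mr")$pixels,
               matrix(0, 8, 8))

  # RGB histology patch vs an independent per-pixel luma-then-rescale oracle
  set.seed(4)
  rgb <- array(runif(10 * 10 * 3), c(10, 10, 3))
  got <- normalize_image(rgb, "histology")$pixels
  luma <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10) {
    luma[i, j] <- 0.2126 * rgb[i, j, 1] + 0.7152 * rgb[i, j, 2] +
      0.0722 * rgb[i, j, 3]
  }
  oracle <- (luma - min(luma)) / (max(luma) - min(luma))
  expect_lt(max(abs(got - oracle)), 1e-6)

  # idempotency
  x <- normalize_image(matrix(runif(64, 2, 9), 8, 8), "mr")$pixels
  expect_lt(max(abs(normalize_image(x, "mr")$pixels - x)), 1e-9)

  expect_error(normalize_image(1:10), "2-D")
})

test_that("foreground_bbox finds a dark square on a light field", {
  px <- matrix(1, 200, 200)
  px[61:160, 41:140] <- 0.05
  bb <- foreground_bbox(hp_image(px, "histology"))
  expect_true(all(abs(bb - c(60, 40, 159, 139)) <= 1))

  # full-coverage foreground -> full-image box
  full <- matrix(0.1, 64, 64)
  full[32, 32] <- 0.9
  bb2 <- foreground_bbox(hp_image(full, "histology"))
  expect_equal(bb2, c(0, 0, 63, 63))

  expect_error(foreground_bbox(hp_image(matrix(0.5, 32, 32), "mr")),
               "empty foreground")
})

test_that("center_zoom scales the box onto the padded frame", {
  px <- matrix(1, 512, 512)
  px[201:300, 151:250] <- 0
  img <- hp_image(px, "histology")
  cz <- center_zoom(img, c(200, 150, 299, 249), pad = 50, out_size = 512)
  expect_equal(cz$zoom$scale, 412 / 100)
  # box center must land at the frame center
  expect_equal(drop(zoom_apply(cz$zoom, cbind(250, 200))), c(256, 256))

  # object already spanning the padded frame -> identity-like transform
  cz2 <- center_zoom(hp_image(px, "histology"), c(50, 50, 461, 461),
                     pad = 50, out_size = 512)
  expect_equal(cz2$zoom$scale, 1)
  expect_lt(max(abs(cz2$zoom$offset)), 1)

  expect_error(center_zoom(img, c(0, 0, 600, 600)), "bbox")
})

test_that("zoom transforms round-trip points to 1e-9", {
  zt <- hp_zoom(2.7, c(13.5, -4.2))
  set.seed(8)
  q <- matrix(runif(2000, 0, 512), ncol = 2)
  back <- zoom_apply(zoom_invert(zt), zoom_apply(zt, q))
  expect_lt(max(abs(back - q)), 1e-9)
})

test_that("apply_zoom_to_points maps valid points and preserves sentinels", {
  pts <- hp_points(rbind(c(5, 5), c(0, 0)), valid = c(TRUE, FALSE))
  zt <- hp_zoom(2, c(10, 10))
  out <- apply_zoom_to_points(pts, zt)
  expect_equal(out$coords[1, ], c(20, 20))
  expect_equal(out$coords[2, ], c(0, 0))
  expect_false(out$valid[2])

  idp <- apply_zoom_to_points(pts, hp_zoom(1, c(0, 0)))
  expect_equal(idp$coords, pts$coords)
})

test_that("pad_points pads with invalid (0,0) sentinels to exactly L", {
  set.seed(2)
  pts <- hp_points(matrix(runif(80, 1, 500), 40, 2))
  pad <- pad_points(pts, 75)
  expect_equal(nrow(pad$coords), 75)
  expect_equal(sum(pad$valid), 40)
  expect_true(all(pad$coords[41:75, ] == 0))

  empty <- pad_points(hp_points(NULL), 75)
  expect_equal(sum(empty$valid), 0)
  expect_equal(nrow(empty$coords), 75)

  full <- hp_points(matrix(runif(150, 1, 500), 75, 2))
  expect_equal(pad_points(full, 75)$coords, full$coords)

  expect_error(pad_points(hp_points(matrix(1, 76, 2)), 75), "raise L")
})

test_that("point CSV round-trips through the id,y,x,class dialect", {
  pts <- hp_points(rbind(c(1.5, 2.5), c(100.25, 30)),
                   class = c("edge", "interior"))
  f <- tempfile(fileext = ".csv")
  write_points(pts, f)
  back <- read_points(f)
  expect_equal(back$coords, pts$coords)
  expect_equal(back$class, pts$class)
})
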