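# DoG candidate detection, contrast/edge filtering, classification and
# minimum-distance thinning.

test_that("constant images produce no candidates; tiny images error", {
  expect_equal(nrow(detect_candidates(matrix(0.5, 64, 64))), 0)
  expect_error(detect_candidates(matrix(runif(100), 10, 10)), "octave")
})

test_that("a Gaussian blob is detected near its center", {
  n <- 96
  yy <- rep(seq_len(n) - 0.5, times = n)
  xx <- rep(seq_len(n) - 0.5, each = n)
  blob <- matrix(exp(-((yy - 48)^2 + (xx - 48)^2) / (2 * 16)), n, n)
  cands <- detect_candidates(blob)
  expect_gt(nrow(cands), 0)
  d <- sqrt((cands$y - 48)^2 + (cands$x - 48)^2)
  expect_lt(min(d), 2)

  # brute-force oracle: scan the explicit DoG stack for a 26-neighborhood
  # extremum near the center in the first octave
  pyr <- hpreg:::build_dog_pyramid(blob)
  found <- FALSE
  for (l in 2:4) {
    D <- pyr[[1]]$dog
    for (r in 46:51) for (c in 46:51) {
      v <- D[[l]][r, c]
      nb <- c()
      for (dl in -1:1) for (dy in -1:1) for (dx in -1:1) {
        if (dl == 0 && dy == 0 && dx == 0) next
        nb <- c(nb, D[[l + dl]][r + dy, c + dx])
      }
      if (v > max(nb) || v < min(nb)) found <- TRUE
    }
  }
  expect_true(found)
})

test_that("candidate sets mirror with the image", {
  ph <- small_phantom()
  px <- ph$moving$pixels
  c1 <- detect_candidates(px)
  c2 <- detect_candidates(px[, ncol(px):1])
  expect_gt(nrow(c1), 10)
  # strong candidates must have a mirrored partner within 1 px
  strong <- c1[c1$contrast >= 0.04, ]
  mx <- ncol(px) - c2$x
  matched <- sapply(seq_len(nrow(strong)), function(i) {
    min(sqrt((c2$y - strong$y[i])^2 + (mx - strong$x[i])^2))
  })
  expect_gt(mean(matched <= 1), 0.9)
})

test_that("filter_contrast keeps candidates at or above the threshold", {
  cands <- data.frame(y = 1:3, x = 1:3, octave = 0L, level = 1L,
                      contrast = c(0.03, 0.04, 0.05), edge_score = 5)
  kept <- filter_contrast(cands, 0.04)
  expect_equal(kept$contrast, c(0.04, 0.05))
  expect_equal(nrow(filter_contrast(cands, 0)), 3)
  expect_equal(nrow(filter_contrast(cands[0, ], 0.04)), 0)
})

test_that("hessian edge score matches the eigenvalue-ratio arithmetic", {
  # eigenvalues (10, 1): Tr^2/Det = 121/10
  expect_equal(hessian_edge_score(10, 1, 0), 12.1)
  # equal eigenvalues -> the minimum, 4
  expect_equal(hessian_edge_score(2, 2, 0), 4)
  # non-positive determinant -> Inf
  expect_equal(hessian_edge_score(1, -1, 0), Inf)
})

test_that("blob centers score near 4 and step edges score far above it", {
  n <- 96
  yy <- rep(seq_len(n) - 0.5, times = n)
  xx <- rep(seq_len(n) - 0.5, each = n)
  blob <- matrix(exp(-((yy - 48)^2 + (xx - 48)^2) / (2 * 16)), n, n)
  cb <- detect_candidates(blob)
  cb <- cb[order(-cb$contrast), ]
  expect_lt(cb$edge_score[1], 6)

  # rendered straight step edge: explicit finite-difference Hessian on the
  # DoG gives a huge trace^2/det ratio at points on the edge
  step <- matrix(0, n, n)
  step[, 49:n] <- 1
  pyr <- hpreg:::build_dog_pyramid(step)
  D <- pyr[[1]]$dog[[3]]
  r <- 48; c <- 49
  dyy <- D[r + 1, c] + D[r - 1, c] - 2 * D[r, c]
  dxx <- D[r, c + 1] + D[r, c - 1] - 2 * D[r, c]
  dxy <- (D[r + 1, c + 1] - D[r + 1, c - 1] - D[r - 1, c + 1] +
            D[r - 1, c - 1]) / 4
  expect_gt(hessian_edge_score(dyy, dxx, dxy), 100)
})

test_that("classify_edges labels exactly ceiling(0.19 n) candidates as edges", {
  set.seed(6)
  cands <- data.frame(y = runif(100), x = runif(100), octave = 0L, level = 1L,
                      contrast = runif(100), edge_score = runif(100, 4, 50))
  cl <- classify_edges(cands)
  expect_equal(sum(cl$class == "edge"), 19)

  one <- classify_edges(cands[1, ])
  expect_equal(one$class, "edge")

  # all-equal scores: deterministic tie-break by contrast then scan order
  ties <- data.frame(y = 1:10, x = 1:10, octave = 0L, level = 1L,
                     contrast = c(5, 5, 1:8), edge_score = 7)
  a <- classify_edges(ties)
  b <- classify_edges(ties)
  expect_identical(a$class, b$class)
  ord <- order(-ties$edge_score, -ties$contrast, seq_len(10))
  expect_equal(which(a$class == "edge"), sort(ord[1:2]))
})

test_that("enforce_min_distance keeps edges over interiors and satisfies
           the pairwise constraint", {
  expect_error(enforce_min_distance(data.frame(), 0), "min_dist")

  one <- data.frame(y = 5, x = 5, octave = 0L, level = 1L, contrast = 1,
                    edge_score = 10, class = "edge")
  expect_equal(n_valid(enforce_min_distance(one, 15)), 1)

  # edge-interior conflict: the interior point dies
  two <- data.frame(y = c(0, 0), x = c(0, 10), octave = 0L, level = 1L,
                    contrast = c(0.1, 9), edge_score = c(10, 4),
                    class = c("edge", "interior"))
  kept <- enforce_min_distance(two, 15)
  expect_equal(n_valid(kept), 1)
  expect_equal(kept$class, "edge")

  # 50 random points against the brute-force pairwise oracle
  set.seed(13)
  many <- data.frame(y = runif(50, 0, 200), x = runif(50, 0, 200),
                     octave = 0L, level = 1L, contrast = runif(50),
                     edge_score = runif(50, 4, 40),
                     class = sample(c("edge", "interior"), 50, TRUE))
  out <- enforce_min_distance(many, 30)
  cc <- valid_coords <- out$coords[out$valid, , drop = FALSE]
  if (nrow(cc) > 1) {
    dd <- as.matrix(dist(cc))
    expect_gte(min(dd[upper.tri(dd)]), 30)
  }
})

test_that("select_landmarks is deterministic, respects its constraints and
           concentrates on phantom contours", {
  ph <- small_phantom()
  a <- select_landmarks(ph$moving, min_dist = 9, max_points = 32)
  b <- select_landmarks(ph$moving, min_dist = 9, max_points = 32)
  expect_identical(a$coords, b$coords)
  expect_identical(a$class, b$class)
  expect_gte(n_valid(a), 10)
  expect_lte(n_valid(a), 32)

  cc <- a$coords[a$valid, , drop = FALSE]
  dd <- as.matrix(dist(cc))
  expect_gte(min(dd[upper.tri(dd)]), 9)
  expect_true(all(attr(a, "contrast") >= 0.04))

  d <- hpreg:::phantom_contour_distance(ph, cc)
  expect_gte(mean(d < 5), 0.6)

  expect_equal(n_valid(select_landmarks(matrix(0.5, 128, 128))), 0)
})

test_that("point count is monotone non-increasing in min_dist", {
  ph <- small_phantom()
  counts <- sapply(c(4, 8, 16, 28), function(d) {
    n_valid(select_landmarks(ph$moving, min_dist = d, max_points = 200))
  })
  expect_true(all(diff(counts) <= 0))
})
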