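# Network forward operations: shapes, analytic reductions, gather/offset/
# similarity/soft-argmax contracts, masking, diagnostics, checkpoints.

test_that("configuration validation and shape bookkeeping", {
  cfg <- model_config()
  expect_equal(cfg$N, 1024)
  expect_error(model_config(image_size = 500), "divisible")
  expect_error(model_config(image_size = 96, patch_size = 6),
               "divisible by 4")
  expect_error(model_config(embed_dim = 30, n_heads = 4), "n_heads")
})

test_that("embed_patches has shape N x d and matches a per-patch oracle", {
  m <- tiny_model()
  img <- noise_image(64, seed = 2)
  emb <- embed_patches(img, "histology", m)
  expect_equal(dim(emb), c(64, 16))

  # zero image, zero position embeddings: all rows equal the bias pathway
  m0 <- m
  m0$weights[["histology.patch.pos"]][] <- 0
  emb0 <- embed_patches(matrix(0, 64, 64), "histology", m0)
  expect_equal(max(apply(emb0, 2, function(col) diff(range(col)))), 0)

  # single patch run through the same weights in isolation equals its row
  emb_np <- embed_patches(img, "histology", m, add_pos = FALSE)
  patch_i <- 3  # second row, first column of the 8x8 patch grid? row-major
  gy <- patch_i %/% 8; gx <- patch_i %% 8
  patch <- img[(gy * 8 + 1):(gy * 8 + 8), (gx * 8 + 1):(gx * 8 + 8)]
  solo_cfg <- model_config(image_size = 8, patch_size = 8, embed_dim = 16,
                           n_blocks = 0, n_heads = 2, L = 4)
  solo_geom <- hpreg:::model_geom(solo_cfg)
  pw <- hpreg:::patch_weights(m$weights, "histology")
  solo <- hpreg:::patch_f(patch, pw, solo_geom, add_pos = FALSE)$y
  expect_lt(max(abs(solo - emb_np[patch_i + 1, ])), 1e-5)
})

test_that("token grid reshape round-trips", {
  x <- matrix(rnorm(64 * 16), 64, 16)
  g <- 8
  arr <- array(0, c(g, g, 16))
  for (t in 1:64) arr[(t - 1) %/% g + 1, (t - 1) %% g + 1, ] <- x[t, ]
  back <- matrix(0, 64, 16)
  for (t in 1:64) back[t, ] <- arr[(t - 1) %/% g + 1, (t - 1) %% g + 1, ]
  expect_identical(back, x)
})

test_that("encoder blocks preserve shape and reduce analytically", {
  m <- tiny_model()
  emb <- embed_patches(noise_image(64, 3), "histology", m)
  out <- local_vit_block(emb, m, "histology", 1)
  expect_equal(dim(out), c(64, 16))

  # identity attention + identity value/output + zero FFN, no layer norm:
  # the block must reduce to x + x
  cfg <- tiny_config(use_layernorm = FALSE)
  mi <- init_model(cfg, seed = 2)
  for (nm in names(mi$weights)) {
    if (grepl("attn.Wv|attn.Wo", nm)) mi$weights[[nm]] <- diag(16)
    if (grepl("attn.b", nm)) mi$weights[[nm]][] <- 0
  }
  x <- matrix(rnorm(64 * 16), 64, 16)
  y <- local_vit_block(x, mi, "histology", 1, attn_override = "identity",
                       ffn_enabled = FALSE)
  expect_lt(max(abs(y - 2 * x)), 1e-10)

  # six such blocks: x * 2^6
  cfg6 <- model_config(image_size = 64, patch_size = 8, embed_dim = 16,
                       n_blocks = 6, n_heads = 2, L = 4,
                       use_layernorm = FALSE)
  m6 <- init_model(cfg6, seed = 2)
  for (nm in names(m6$weights)) {
    if (grepl("attn.Wv|attn.Wo", nm)) m6$weights[[nm]] <- diag(16)
    if (grepl("attn.b", nm)) m6$weights[[nm]][] <- 0
  }
  y6 <- encode(x, m6, "histology", attn_override = "identity",
               ffn_enabled = FALSE)
  expect_lt(max(abs(y6 - 64 * x)), 1e-8)
})

test_that("encode with zero blocks is the identity and branches differ", {
  cfg0 <- tiny_config()
  cfg0$n_blocks <- 0L
  m0 <- structure(list(config = cfg0, weights = init_model(cfg0)$weights,
                       branches = c("histology", "mr")), class = "hp_model")
  x <- matrix(rnorm(64 * 16), 64, 16)
  expect_equal(unclass(encode(x, m0, "histology"))[, ], x)

  m <- tiny_model()
  yh <- encode(x, m, "histology")
  ym <- encode(x, m, "mr")
  expect_gt(max(abs(yh - ym)), 0)
})

test_that("gather follows the row-major patch index and flags invalids", {
  m <- tiny_model()
  enc <- encode(embed_patches(noise_image(64, 4), "histology", m), m)

  X0 <- pad_points(hp_points(rbind(c(0, 0))), 4)
  g0 <- gather_landmark_embeddings(enc, X0, 8)
  expect_equal(g0[1, ], unclass(enc)[1, ])

  # brute-force containment oracle over all patches
  X <- pad_points(hp_points(rbind(c(37, 5), c(12, 61))), 4)
  gg <- gather_landmark_embeddings(enc, X, 8)
  for (i in 1:2) {
    hit <- NA
    for (j in 0:63) {
      gy <- j %/% 8; gx <- j %% 8
      if (X$coords[i, 1] >= gy * 8 && X$coords[i, 1] < (gy + 1) * 8 &&
          X$coords[i, 2] >= gx * 8 && X$coords[i, 2] < (gx + 1) * 8) hit <- j
    }
    expect_equal(gg[i, ], unclass(enc)[hit + 1, ])
  }

  allpad <- pad_points(hp_points(NULL), 4)
  ga <- gather_landmark_embeddings(enc, allpad, 8)
  expect_true(all(!attr(ga, "valid")))

  Xout <- hp_points(rbind(c(100, 5)))
  expect_error(gather_landmark_embeddings(enc, pad_points(Xout, 4), 8),
               "outside")
})

test_that("offsets follow (X mod p) - floor(p/2) with the right range", {
  X <- pad_points(hp_points(rbind(c(8, 8), c(37, 5))), 4)
  O <- compute_offsets(X, 16)
  expect_equal(O[1, ], c(-0, -0) + 0)
  expect_equal(O[2, ], c(37 %% 16 - 8, 5 %% 16 - 8))

  Xc <- hp_points(rbind(c(8, 8)))
  expect_equal(compute_offsets(pad_points(Xc, 1), 16)[1, ], c(0, 0))

  set.seed(31)
  Xr <- hp_points(matrix(runif(2000, 0, 512), 1000, 2))
  Or <- compute_offsets(Xr, 16)
  expect_true(all(Or >= -8 & Or < 8))
})

test_that("similarity is row-stochastic with hand-checkable values", {
  S <- similarity(matrix(c(0, 0), 1, 2), rbind(c(0, 0), c(0, 0)))
  expect_equal(drop(S), c(0.5, 0.5))

  # logits (0, ln 3) -> (0.25, 0.75)
  Pm <- matrix(c(1, 0), 1, 2)
  Pf <- rbind(c(0, 5), c(log(3), 7))
  S2 <- similarity(Pm, Pf)
  expect_equal(drop(S2), c(0.25, 0.75), tolerance = 1e-12)

  # scaled orthogonal keys: mass concentrates on the matching key
  d <- 8
  keys <- diag(d) * 100
  q <- matrix(keys[3, ], 1, d)
  S3 <- similarity(q, keys)
  expect_gt(S3[1, 3], 0.99)

  set.seed(7)
  S4 <- similarity(matrix(rnorm(3 * 4), 3, 4), matrix(rnorm(16 * 4), 16, 4))
  expect_lt(max(abs(rowSums(S4) - 1)), 1e-6)
  expect_true(all(S4 >= 0 & S4 <= 1))

  expect_error(similarity(matrix(0, 1, 3), matrix(0, 4, 2)), "dimensions")
})

test_that("soft_argmax reproduces centers, midpoints and the image center", {
  p <- 16; size <- 512; N <- (size / p)^2
  S <- matrix(0, 1, N); S[1, 200] <- 1
  j0 <- 199; g <- size / p
  expect_equal(drop(soft_argmax(S, p, size)),
               c(p / 2 + p * (j0 %/% g), p / 2 + p * (j0 %% g)))

  Su <- matrix(1 / N, 1, N)
  expect_equal(drop(soft_argmax(Su, p, size)), c(256, 256))

  Sm <- matrix(0, 1, N); Sm[1, 1] <- 0.5; Sm[1, N] <- 0.5
  expect_equal(drop(soft_argmax(Sm, p, size)), c(256, 256))
  Sm2 <- matrix(0, 1, N); Sm2[1, 1] <- 0.5; Sm2[1, 2] <- 0.5
  expect_equal(drop(soft_argmax(Sm2, p, size)), c(8, 16))
})

test_that("predict_points equals the piecewise composition and masks padding", {
  m <- tiny_model()
  cfg <- m$config
  Mim <- noise_image(64, 10); Fim <- noise_image(64, 11)
  X <- pad_points(hp_points(rbind(c(10, 20), c(37, 5), c(60, 60))), 4)
  Y <- predict_points(Mim, Fim, X, m)

  emb_m <- embed_patches(Mim, "histology", m)
  emb_f <- embed_patches(Fim, "mr", m)
  enc_m <- encode(emb_m, m); enc_f <- encode(emb_f, m)
  Pm <- gather_landmark_embeddings(enc_m, X, cfg$patch_size)
  O <- compute_offsets(X, cfg$patch_size)
  S <- similarity(Pm, enc_f)
  Yhat <- soft_argmax(S, cfg$patch_size, cfg$image_size)
  Ycomp <- Yhat + O
  Ycomp[!X$valid, ] <- 0
  expect_lt(max(abs(unclass(Y)[, 1:2] - Ycomp)), 1e-5)

  # all-sentinel input -> all-zero output
  Y0 <- predict_points(Mim, Fim, pad_points(hp_points(NULL), 4), m)
  expect_true(all(unclass(Y0)[, 1:2] == 0))

  # perturbing sentinel entries never changes valid rows
  X2 <- X
  X2$coords[4, ] <- c(33, 44)  # still flagged invalid
  Y2 <- predict_points(Mim, Fim, X2, m)
  expect_equal(unclass(Y2)[1:3, ], unclass(Y)[1:3, ])
  expect_equal(unclass(Y2)[4, ], c(0, 0))

  # determinism
  Yb <- predict_points(Mim, Fim, X, m)
  expect_identical(unclass(Y)[, ], unclass(Yb)[, ])

  # valid rows live inside the soft-argmax + offset range
  v <- unclass(Y)[X$valid, ]
  p <- cfg$patch_size
  expect_true(all(v >= p / 2 - floor(p / 2)))
  expect_true(all(v < cfg$image_size - p / 2 + p - floor(p / 2)))
})

test_that("similarity heatmap reshapes a row onto the patch grid", {
  p <- 8; size <- 64; N <- 64
  S <- matrix(0, 2, N); S[1, 11] <- 1; S[2, ] <- 1 / N
  hm <- similarity_heatmap(S, 1, p, size)
  grid <- attr(hm, "grid")
  expect_equal(sum(grid), 1)
  # argmax cell center equals the soft-argmax of the one-hot row
  am <- which(grid == max(grid), arr.ind = TRUE)
  center <- c(p / 2 + p * (am[1] - 1), p / 2 + p * (am[2] - 1))
  expect_equal(drop(soft_argmax(S[1, , drop = FALSE], p, size)), center)

  hu <- similarity_heatmap(S, 2, p, size)
  expect_equal(diff(range(attr(hu, "grid"))), 0)
  expect_error(similarity_heatmap(S, 5, p, size), "row")
})

test_that("parameter count matches an exact hand count and the tensors", {
  cfg <- tiny_config()
  m <- tiny_model()
  expect_equal(parameter_count(cfg), sum(sapply(m$weights, length)))

  # hand count for one branch of a minimal config
  c1 <- model_config(image_size = 16, patch_size = 8, embed_dim = 8,
                     n_blocks = 1, n_heads = 2, L = 2)
  patch <- (2 * 2 * 1 * 64 + 64) + (2 * 2 * 64 * 64 + 64) +
    (2 * 2 * 64 * 8 + 8)
  pos <- 4 * 8
  ln <- 2 * (2 * 8)
  attn <- 4 * (8 * 8 + 8)
  ffn <- (8 * 32 + 32) + (9 * 32 + 32) + (32 * 8 + 8)
  expect_equal(parameter_count(c1), 2 * (patch + pos + ln + attn + ffn))
})

test_that("checkpoints round-trip and verify shapes", {
  m <- tiny_model()
  f <- tempfile(fileext = ".rds")
  save_model(m, f)
  back <- load_model(f)
  expect_equal(back$config$embed_dim, 16)
  expect_identical(back$weights, m$weights)

  # corrupt a tensor shape
  bad <- readRDS(f)
  bad$weights[["histology.patch.W1"]] <- matrix(0, 2, 2)
  f2 <- tempfile(fileext = ".rds")
  saveRDS(bad, f2)
  expect_error(load_model(f2), "shaped inconsistently")
})
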