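# Shared fixtures, generated in code and memoized for the test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  got <- .fixtures[[key]]
  if (is.null(got)) {
    got <- force(expr)
    .fixtures[[key]] <- got
  }
  got
}

# a small phantom (fast; most structural tests)
small_phantom <- function(seed = 11) {
  memo(paste0("ph128_", seed),
       generate_phantom(seed, size = 128, n_gt_points = 20))
}

# a full-size phantom for landmark tests
big_phantom <- function(seed = 3) {
  memo(paste0("ph512_", seed), generate_phantom(seed, size = 512))
}

# a phantom packaged as a training slide
phantom_to_slide_fixture <- function(seed = 11, size = 128) {
  memo(paste0("slide_", seed, "_", size),
       hpreg:::phantom_to_slide(generate_phantom(seed, size = size,
                                                 n_gt_points = 16)))
}

# tiny model configuration exercised by most network tests
tiny_config <- function(...) {
  model_config(image_size = 64, patch_size = 8, embed_dim = 16,
               n_blocks = 2, n_heads = 2, L = 4, ...)
}

tiny_model <- function(seed = 5, ...) {
  init_model(tiny_config(...), seed = seed)
}

# deterministic pseudo-random test image
noise_image <- function(n, seed = 1) {
  with_seed <- getFromNamespace("with_seed", "hpreg")
  with_seed(seed, matrix(stats::runif(n * n), n, n))
}

# independent naive-loop implementations of the point-head equations,
# used as oracles against the vectorized implementation
naive_gather <- function(enc_m, X, p, g) {
  L <- nrow(X$coords)
  out <- matrix(0, L, ncol(enc_m))
  for (i in seq_len(L)) {
    idx <- if (X$valid[i]) {
      floor(X$coords[i, 1] / p) * g + floor(X$coords[i, 2] / p)
    } else 0
    out[i, ] <- enc_m[idx + 1, ]
  }
  out
}

naive_offsets <- function(X, p) {
  L <- nrow(X$coords)
  out <- matrix(0, L, 2)
  for (i in seq_len(L)) {
    for (a in 1:2) {
      out[i, a] <- (X$coords[i, a] %% p) - floor(p / 2)
    }
  }
  out
}

naive_similarity <- function(Pm, Pf) {
  L <- nrow(Pm); N <- nrow(Pf)
  S <- matrix(0, L, N)
  for (i in seq_len(L)) {
    z <- numeric(N)
    for (j in seq_len(N)) z[j] <- sum(Pm[i, ] * Pf[j, ])
    e <- exp(z - max(z))
    S[i, ] <- e / sum(e)
  }
  S
}

naive_soft_argmax <- function(S, p, image_size) {
  g <- image_size %/% p
  L <- nrow(S)
  out <- matrix(0, L, 2)
  for (i in seq_len(L)) {
    for (j in seq_len(ncol(S))) {
      j0 <- j - 1
      cy <- p / 2 + p * (j0 %/% g)
      cx <- p / 2 + p * (j0 %% g)
      out[i, 1] <- out[i, 1] + S[i, j] * cy
      out[i, 2] <- out[i, 2] + S[i, j] * cx
    }
  }
  out
}
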