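# Network layer primitives with hand-written forward/backward passes.
# Everything is dense matrix algebra: tokens are rows of an N x d matrix in
# row-major patch order, feature maps are (H*W) x C matrices in row-major
# pixel order.  Caches returned by *_f functions carry exactly what the
# paired *_b function needs.

# add / multiply a row vector into every row of a matrix (fast broadcast)
bcast <- function(v, n) matrix(rep(v, each = n), n)

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

softmax_rows <- function(z) .softmax_rows(z)

# d softmax / dlogits applied to upstream dS (row-wise softmax jacobian)
softmax_rows_backward <- function(dS, S) .softmax_rows_bwd(dS, S)

# ---- layer norm ------------------------------------------------------------

ln_f <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  n <- nrow(x)
  list(y = xhat * rep(g, each = n) + rep(b, each = n),
       xhat = xhat, inv = inv, g = g)
}

ln_b <- function(dy, cache) {
  xhat <- cache$xhat
  n <- nrow(dy)
  dxhat <- dy * rep(cache$g, each = n)
  dx <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

# ---- multi-head self-attention --------------------------------------------

attn_f <- function(x, W, h, override = NULL) {
  N <- nrow(x); d <- ncol(x); dh <- d %/% h
  Q <- x %*% W$Wq + rep(W$bq, each = N)
  K <- x %*% W$Wk + rep(W$bk, each = N)
  V <- x %*% W$Wv + rep(W$bv, each = N)
  cat <- matrix(0, N, d)
  A <- vector("list", h)
  s <- sqrt(dh)
  for (i in seq_len(h)) {
    idx <- ((i - 1) * dh + 1):(i * dh)
    if (identical(override, "identity")) {
      cat[, idx] <- V[, idx]
    } else {
      Ai <- softmax_rows(Q[, idx, drop = FALSE] %*%
                           t(K[, idx, drop = FALSE]) / s)
      A[[i]] <- Ai
      cat[, idx] <- Ai %*% V[, idx, drop = FALSE]
    }
  }
  list(y = cat %*% W$Wo + rep(W$bo, each = N),
       x = x, Q = Q, K = K, V = V, A = A, cat = cat, h = h, s = s,
       override = override)
}

attn_b <- function(dy, cache, W) {
  x <- cache$x; h <- cache$h; s <- cache$s
  N <- nrow(x); d <- ncol(x); dh <- d %/% h
  dWo <- crossprod(cache$cat, dy)
  dbo <- colSums(dy)
  dcat <- dy %*% t(W$Wo)
  dQ <- matrix(0, N, d); dK <- matrix(0, N, d); dV <- matrix(0, N, d)
  for (i in seq_len(h)) {
    idx <- ((i - 1) * dh + 1):(i * dh)
    dOi <- dcat[, idx, drop = FALSE]
    if (identical(cache$override, "identity")) {
      dV[, idx] <- dOi
    } else {
      Ai <- cache$A[[i]]
      Vi <- cache$V[, idx, drop = FALSE]
      dA <- dOi %*% t(Vi)
      dV[, idx] <- crossprod(Ai, dOi)
      dZ <- softmax_rows_backward(dA, Ai)
      dQ[, idx] <- dZ %*% cache$K[, idx, drop = FALSE] / s
      dK[, idx] <- crossprod(dZ, cache$Q[, idx, drop = FALSE]) / s
    }
  }
  dx <- dQ %*% t(W$Wq) + dK %*% t(W$Wk) + dV %*% t(W$Wv)
  list(dx = dx,
       dWq = crossprod(x, dQ), dbq = colSums(dQ),
       dWk = crossprod(x, dK), dbk = colSums(dK),
       dWv = crossprod(x, dV), dbv = colSums(dV),
       dWo = dWo, dbo = dbo)
}

# ---- locality-preserving feed-forward (1x1 expand, 3x3 depthwise, 1x1) ----

# neighbor index table for a g x g token grid: N x 9, NA outside the grid.
neighbor_index <- function(g) {
  t0 <- 0:(g * g - 1)
  gy <- t0 %/% g; gx <- t0 %% g
  nbr <- matrix(NA_integer_, g * g, 9)
  o <- 1L
  for (dy in -1:1) for (dx in -1:1) {
    ny <- gy + dy; nx <- gx + dx
    ok <- ny >= 0 & ny < g & nx >= 0 & nx < g
    col <- rep(NA_integer_, g * g)
    col[ok] <- ny[ok] * g + nx[ok] + 1L
    nbr[, o] <- col
    o <- o + 1L
  }
  nbr
}

# 0-padded neighbor table for the C++ kernel (0 marks off-grid neighbors)
dw_tables <- function(g) {
  nbr <- neighbor_index(g)
  nbr[is.na(nbr)] <- 0L
  nbr
}

ffn_f <- function(x, W, dwt) {
  N <- nrow(x)
  h1 <- x %*% W$W1 + rep(W$b1, each = N)
  a1 <- .gelu_fwd(h1)
  z2 <- .dwconv_fwd(a1$y, W$Wdw, W$bdw, dwt)
  a2 <- .gelu_fwd(z2)
  list(y = a2$y %*% W$W2 + rep(W$b2, each = N),
       x = x, h1 = h1, phi1 = a1$phi, g1 = a1$y, z2 = z2, phi2 = a2$phi,
       g2 = a2$y)
}

ffn_b <- function(dy, cache, W, dwt) {
  dg2 <- dy %*% t(W$W2)
  dW2 <- crossprod(cache$g2, dy)
  db2 <- colSums(dy)
  dz2 <- .gelu_bwd(dg2, cache$z2, cache$phi2)
  dw <- .dwconv_bwd(dz2, cache$g1, W$Wdw, dwt)
  dh1 <- .gelu_bwd(dw$dx, cache$h1, cache$phi1)
  list(dx = dh1 %*% t(W$W1),
       dW1 = crossprod(cache$x, dh1), db1 = colSums(dh1),
       dWdw = dw$dW, dbdw = dw$db,
       dW2 = dW2, db2 = db2)
}

# ---- encoder block ---------------------------------------------------------

# Weight name helpers: flat list keyed "branch.blkK.part.name"
wname <- function(branch, ...) paste(c(branch, ...), collapse = ".")

block_weights <- function(weights, branch, k) {
  p <- function(part, nm) weights[[wname(branch, paste0("blk", k),
                                         paste0(part, ".", nm))]]
  list(ln1_g = p("ln1", "g"), ln1_b = p("ln1", "b"),
       attn = list(Wq = p("attn", "Wq"), bq = p("attn", "bq"),
                   Wk = p("attn", "Wk"), bk = p("attn", "bk"),
                   Wv = p("attn", "Wv"), bv = p("attn", "bv"),
                   Wo = p("attn", "Wo"), bo = p("attn", "bo")),
       ln2_g = p("ln2", "g"), ln2_b = p("ln2", "b"),
       ffn = list(W1 = p("ffn", "W1"), b1 = p("ffn", "b1"),
                  Wdw = p("ffn", "Wdw"), bdw = p("ffn", "bdw"),
                  W2 = p("ffn", "W2"), b2 = p("ffn", "b2")))
}

block_f <- function(x, bw, use_ln, h, dwt, attn_override = NULL,
                    ffn_enabled = TRUE) {
  if (use_ln) {
    l1 <- ln_f(x, bw$ln1_g, bw$ln1_b)
    a_in <- l1$y
  } else {
    l1 <- NULL
    a_in <- x
  }
  at <- attn_f(a_in, bw$attn, h, override = attn_override)
  x1 <- x + at$y
  if (use_ln) {
    l2 <- ln_f(x1, bw$ln2_g, bw$ln2_b)
    f_in <- l2$y
  } else {
    l2 <- NULL
    f_in <- x1
  }
  if (ffn_enabled) {
    ff <- ffn_f(f_in, bw$ffn, dwt)
    x2 <- x1 + ff$y
  } else {
    ff <- NULL
    x2 <- x1
  }
  list(y = x2, l1 = l1, at = at, x1 = x1, l2 = l2, ff = ff)
}

# Accumulate into a gradient environment keyed by weight name.
gacc <- function(G, name, val) {
  if (is.null(G[[name]])) G[[name]] <- val else G[[name]] <- G[[name]] + val
  invisible(NULL)
}

block_b <- function(dy, cache, bw, use_ln, dwt, G, branch, k) {
  nm <- function(part, x) wname(branch, paste0("blk", k), paste0(part, ".", x))
  dx1 <- dy
  if (!is.null(cache$ff)) {
    fb <- ffn_b(dy, cache$ff, bw$ffn, dwt)
    gacc(G, nm("ffn", "W1"), fb$dW1); gacc(G, nm("ffn", "b1"), fb$db1)
    gacc(G, nm("ffn", "Wdw"), fb$dWdw); gacc(G, nm("ffn", "bdw"), fb$dbdw)
    gacc(G, nm("ffn", "W2"), fb$dW2); gacc(G, nm("ffn", "b2"), fb$db2)
    if (use_ln) {
      lb <- ln_b(fb$dx, cache$l2)
      gacc(G, nm("ln2", "g"), lb$dg); gacc(G, nm("ln2", "b"), lb$db)
      dx1 <- dx1 + lb$dx
    } else {
      dx1 <- dx1 + fb$dx
    }
  }
  ab <- attn_b(dx1, cache$at, bw$attn)
  gacc(G, nm("attn", "Wq"), ab$dWq); gacc(G, nm("attn", "bq"), ab$dbq)
  gacc(G, nm("attn", "Wk"), ab$dWk); gacc(G, nm("attn", "bk"), ab$dbk)
  gacc(G, nm("attn", "Wv"), ab$dWv); gacc(G, nm("attn", "bv"), ab$dbv)
  gacc(G, nm("attn", "Wo"), ab$dWo); gacc(G, nm("attn", "bo"), ab$dbo)
  dx <- dx1
  if (use_ln) {
    lb <- ln_b(ab$dx, cache$l1)
    gacc(G, nm("ln1", "g"), lb$dg); gacc(G, nm("ln1", "b"), lb$db)
    dx <- dx + lb$dx
  } else {
    dx <- dx + ab$dx
  }
  dx
}

# ---- patch CNN -------------------------------------------------------------

# flat indices (1-based) of non-overlapping b x b blocks over an H x W grid;
# blocks row-major, within-block pixels row-major.
block_index_mat <- function(H, W, b) {
  gy <- rep(seq(0, H - b, by = b), each = W %/% b)
  gx <- rep(seq(0, W - b, by = b), times = H %/% b)
  oy <- rep(0:(b - 1), each = b)
  ox <- rep(0:(b - 1), times = b)
  outer(gy, oy, "+") * W + outer(gx, ox, "+") + 1L
}

im2col_no <- function(map, idx) {
  nb <- nrow(idx); b2 <- ncol(idx); C <- ncol(map)
  out <- matrix(0, nb, b2 * C)
  for (m in seq_len(b2)) {
    out[, ((m - 1) * C + 1):(m * C)] <- map[idx[, m], , drop = FALSE]
  }
  out
}

col2im_no <- function(cols, idx, C, npix) {
  map <- matrix(0, npix, C)
  for (m in seq_len(ncol(idx))) {
    map[idx[, m], ] <- cols[, ((m - 1) * C + 1):(m * C), drop = FALSE]
  }
  map
}

# memoized per-config geometry (index tables, token grid, patch centers)
.geom_cache <- new.env(parent = emptyenv())

model_geom <- function(cfg) {
  key <- paste(cfg$image_size, cfg$patch_size, sep = "_")
  got <- .geom_cache[[key]]
  if (!is.null(got)) return(got)
  S <- cfg$image_size; p <- cfg$patch_size
  g <- S %/% p
  N <- g * g
  j0 <- 0:(N - 1)
  centers <- cbind(p / 2 + p * (j0 %/% g), p / 2 + p * (j0 %% g))
  geom <- list(
    idx1 = block_index_mat(S, S, 2L),
    idx2 = block_index_mat(S %/% 2, S %/% 2, 2L),
    idx3 = block_index_mat(S %/% 4, S %/% 4, p %/% 4),
    npix1 = (S %/% 2)^2, npix2 = (S %/% 4)^2,
    nbr = neighbor_index(g),
    dwt = dw_tables(g),
    g = g, N = N, centers = centers
  )
  .geom_cache[[key]] <- geom
  geom
}

patch_weights <- function(weights, branch) {
  p <- function(nm) weights[[wname(branch, "patch", nm)]]
  list(W1 = p("W1"), b1 = p("b1"), W2 = p("W2"), b2 = p("b2"),
       W3 = p("W3"), b3 = p("b3"), pos = p("pos"))
}

patch_f <- function(px, pw, geom, add_pos = TRUE) {
  map0 <- matrix(as.vector(t(px)), ncol = 1)
  X1 <- im2col_no(map0, geom$idx1)
  Z1 <- X1 %*% pw$W1 + rep(pw$b1, each = nrow(X1))
  A1 <- pmax(Z1, 0)
  X2 <- im2col_no(A1, geom$idx2)
  Z2 <- X2 %*% pw$W2 + rep(pw$b2, each = nrow(X2))
  A2 <- pmax(Z2, 0)
  X3 <- im2col_no(A2, geom$idx3)
  Z3 <- X3 %*% pw$W3 + rep(pw$b3, each = nrow(X3))
  emb <- if (add_pos) Z3 + pw$pos else Z3
  list(y = emb, X1 = X1, Z1 = Z1, X2 = X2, Z2 = Z2, X3 = X3,
       add_pos = add_pos)
}

patch_b <- function(demb, cache, pw, geom, G, branch) {
  nm <- function(x) wname(branch, "patch", x)
  if (cache$add_pos) gacc(G, nm("pos"), demb)
  dZ3 <- demb
  gacc(G, nm("W3"), crossprod(cache$X3, dZ3))
  gacc(G, nm("b3"), colSums(dZ3))
  dX3 <- dZ3 %*% t(pw$W3)
  dA2 <- col2im_no(dX3, geom$idx3, 64L, geom$npix2)
  dZ2 <- dA2 * (cache$Z2 > 0)
  gacc(G, nm("W2"), crossprod(cache$X2, dZ2))
  gacc(G, nm("b2"), colSums(dZ2))
  dX2 <- dZ2 %*% t(pw$W2)
  dA1 <- col2im_no(dX2, geom$idx2, 64L, geom$npix1)
  dZ1 <- dA1 * (cache$Z1 > 0)
  gacc(G, nm("W1"), crossprod(cache$X1, dZ1))
  gacc(G, nm("b1"), colSums(dZ1))
  invisible(NULL)
}

# ---- full encoder forward/backward ----------------------------------------

encoder_f <- function(px, weights, branch, cfg, geom, attn_override = NULL,
                      ffn_enabled = TRUE) {
  pw <- patch_weights(weights, branch)
  pc <- patch_f(px, pw, geom)
  x <- pc$y
  blocks <- vector("list", cfg$n_blocks)
  for (k in seq_len(cfg$n_blocks)) {
    bw <- block_weights(weights, branch, k)
    bc <- block_f(x, bw, cfg$use_layernorm, cfg$n_heads, geom$dwt,
                  attn_override = attn_override, ffn_enabled = ffn_enabled)
    blocks[[k]] <- bc
    x <- bc$y
  }
  list(y = x, patch = pc, blocks = blocks, branch = branch)
}

encoder_b <- function(dy, cache, weights, cfg, geom, G) {
  branch <- cache$branch
  dx <- dy
  for (k in rev(seq_len(cfg$n_blocks))) {
    bw <- block_weights(weights, branch, k)
    dx <- block_b(dx, cache$blocks[[k]], bw, cfg$use_layernorm, geom$dwt, G,
                  branch, k)
  }
  pw <- patch_weights(weights, branch)
  patch_b(dx, cache$patch, pw, geom, G, branch)
  invisible(NULL)
}

# ---- point head ------------------------------------------------------------

# row-major patch index (0-based) for coords matrix
patch_index0 <- function(coords, p, g) {
  floor(coords[, 1] / p) * g + floor(coords[, 2] / p)
}

# Full forward pass for one example.  X must be padded to length L.
# Returns Y (L x 2) plus caches for the backward pass.
forward_pass <- function(weights, cfg, M_px, F_px, X, moving_branch,
                         fixed_branch, temperature = 1) {
  geom <- model_geom(cfg)
  stopifnot(nrow(M_px) == cfg$image_size, nrow(F_px) == cfg$image_size)
  enc_m <- encoder_f(M_px, weights, moving_branch, cfg, geom)
  enc_f <- encoder_f(F_px, weights, fixed_branch, cfg, geom)
  coords <- X$coords
  valid <- X$valid
  if (length(valid) != cfg$L) stop("forward_pass: X must be padded to L")
  ok <- valid & coords[, 1] >= 0 & coords[, 1] < cfg$image_size &
    coords[, 2] >= 0 & coords[, 2] < cfg$image_size
  if (any(valid & !ok)) stop("forward_pass: landmark outside image bounds")
  pidx <- rep(0, cfg$L)
  pidx[valid] <- patch_index0(coords[valid, , drop = FALSE], cfg$patch_size,
                              geom$g)
  Pm_prime <- enc_m$y[pidx + 1, , drop = FALSE]
  O <- (coords %% cfg$patch_size) - floor(cfg$patch_size / 2)
  logits <- Pm_prime %*% t(enc_f$y) / temperature
  S <- softmax_rows(logits)
  Yhat <- S %*% geom$centers
  Y <- Yhat + O
  Y[!valid, ] <- 0
  list(Y = Y, S = S, Yhat = Yhat, O = O, pidx = pidx, valid = valid,
       Pm_prime = Pm_prime, enc_m = enc_m, enc_f = enc_f, geom = geom,
       temperature = temperature,
       moving_branch = moving_branch, fixed_branch = fixed_branch)
}

# Backward from dY (L x 2) to a gradient environment over all weight names.
backward_pass <- function(fw, dY, weights, cfg, G = NULL) {
  G <- G %||% new.env(parent = emptyenv())
  geom <- fw$geom
  dY <- dY * fw$valid  # column-wise recycling over the 2 coord columns
  dS <- dY %*% t(geom$centers)
  dZ <- softmax_rows_backward(dS, fw$S) / fw$temperature
  dPm_prime <- dZ %*% fw$enc_f$y
  denc_f <- crossprod(dZ, fw$Pm_prime)
  denc_m <- matrix(0, geom$N, cfg$embed_dim)
  for (i in which(fw$valid)) {
    r <- fw$pidx[i] + 1
    denc_m[r, ] <- denc_m[r, ] + dPm_prime[i, ]
  }
  encoder_b(denc_f, fw$enc_f, weights, cfg, geom, G)
  encoder_b(denc_m, fw$enc_m, weights, cfg, geom, G)
  G
}

# materialize a gradient environment as a flat list aligned with `weights`,
# zeros for untouched tensors
grads_as_list <- function(G, weights) {
  out <- vector("list", length(weights))
  names(out) <- names(weights)
  for (nm in names(weights)) {
    g <- G[[nm]]
    out[[nm]] <- if (is.null(g)) weights[[nm]] * 0 else g
  }
  out
}
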