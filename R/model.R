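# Public surface of the homologous point network: configuration, weight
# initialization, the forward-pass operations, the similarity heatmap
# diagnostic, parameter counting and checkpoint I/O.
#
# Architecture: each image branch slices its input into p x p patches, embeds
# each patch with a small CNN (two stride-2 2x2 convolutions with 64 channels,
# then a (p/4) x (p/4) convolution to d channels) plus a learned position
# embedding, and encodes the N x d token matrix with a stack of
# locality-preserving transformer blocks (global multi-head attention, then a
# convolutional feed-forward: 1x1 expansion to 4d, 3x3 depthwise, 1x1
# projection on the sqrt(N) x sqrt(N) token grid).  The histology and MR
# branches have disjoint weights.  The point head gathers the encoded moving
# patch under each landmark, takes row-wise softmax dot-product similarity
# against all encoded fixed patches, soft-argmaxes over the patch-center
# meshgrid, and adds the landmark's offset from its patch center.

#' Network configuration
#'
#' @param image_size input side length (default 512).
#' @param patch_size patch side p; must divide `image_size` and be divisible
#'   by 4 (default 16).
#' @param embed_dim embedding width d (default 128).
#' @param n_blocks encoder blocks per branch (default 6).
#' @param n_heads attention heads (default 4; must divide `embed_dim`).
#' @param L fixed landmark list length (default 75).
#' @param ffn_expansion feed-forward expansion factor (fixed at 4).
#' @param use_layernorm pre-norm layer normalization in the encoder blocks
#'   (default `TRUE`).
#' @param temperature softmax temperature of the similarity head (default 1,
#'   i.e. raw dot products as printed; no 1/sqrt(d) scaling).
#' @return object of class `hp_model_config`.
#' @export
model_config <- function(image_size = 512L, patch_size = 16L, embed_dim = 128L,
                         n_blocks = 6L, n_heads = 4L, L = 75L,
                         ffn_expansion = 4L, use_layernorm = TRUE,
                         temperature = 1) {
  cfg <- list(image_size = as.integer(image_size),
              patch_size = as.integer(patch_size),
              embed_dim = as.integer(embed_dim),
              n_blocks = as.integer(n_blocks),
              n_heads = as.integer(n_heads),
              L = as.integer(L),
              ffn_expansion = as.integer(ffn_expansion),
              use_layernorm = isTRUE(use_layernorm),
              temperature = as.numeric(temperature))
  if (cfg$image_size %% cfg$patch_size != 0) {
    stop("model_config: image_size must be divisible by patch_size")
  }
  if (cfg$patch_size %% 4 != 0) {
    stop("model_config: patch_size must be divisible by 4")
  }
  if (cfg$embed_dim %% cfg$n_heads != 0) {
    stop("model_config: embed_dim must be divisible by n_heads")
  }
  if (cfg$ffn_expansion != 4L) {
    stop("model_config: ffn_expansion is fixed at 4")
  }
  cfg$N <- (cfg$image_size %/% cfg$patch_size)^2
  structure(cfg, class = "hp_model_config")
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize network weights
#'
#' Glorot-uniform matrices, zero biases, unit/zero layer-norm parameters and
#' small-normal position embeddings, for both branches (weights are never
#' shared across branches).
#'
#' @param config `hp_model_config`.
#' @param seed integer seed.
#' @param branches branch names (default histology + mr).
#' @return object of class `hp_model`: list with `config` and flat named
#'   `weights`.
#' @export
init_model <- function(config, seed = 1L,
                       branches = c("histology", "mr")) {
  cfg <- config
  d <- cfg$embed_dim; p <- cfg$patch_size; e <- cfg$ffn_expansion
  w <- list()
  with_seed(seed, {
    for (br in branches) {
      w[[wname(br, "patch", "W1")]] <- glorot(4, 64)
      w[[wname(br, "patch", "b1")]] <- numeric(64)
      w[[wname(br, "patch", "W2")]] <- glorot(4 * 64, 64)
      w[[wname(br, "patch", "b2")]] <- numeric(64)
      w[[wname(br, "patch", "W3")]] <- glorot((p %/% 4)^2 * 64, d)
      w[[wname(br, "patch", "b3")]] <- numeric(d)
      w[[wname(br, "patch", "pos")]] <- matrix(stats::rnorm(cfg$N * d, 0, 0.02),
                                               cfg$N, d)
      for (k in seq_len(cfg$n_blocks)) {
        nm <- function(part, x) wname(br, paste0("blk", k),
                                      paste0(part, ".", x))
        w[[nm("ln1", "g")]] <- rep(1, d); w[[nm("ln1", "b")]] <- numeric(d)
        for (m in c("Wq", "Wk", "Wv", "Wo")) w[[nm("attn", m)]] <- glorot(d, d)
        for (m in c("bq", "bk", "bv", "bo")) w[[nm("attn", m)]] <- numeric(d)
        w[[nm("ln2", "g")]] <- rep(1, d); w[[nm("ln2", "b")]] <- numeric(d)
        w[[nm("ffn", "W1")]] <- glorot(d, e * d)
        w[[nm("ffn", "b1")]] <- numeric(e * d)
        w[[nm("ffn", "Wdw")]] <- matrix(stats::rnorm(9 * e * d, 0,
                                                     sqrt(2 / 9)), 9, e * d)
        w[[nm("ffn", "bdw")]] <- numeric(e * d)
        w[[nm("ffn", "W2")]] <- glorot(e * d, d)
        w[[nm("ffn", "b2")]] <- numeric(d)
      }
    }
  })
  structure(list(config = cfg, weights = w, branches = branches),
            class = "hp_model")
}

#' @export
print.hp_model <- function(x, ...) {
  cat(sprintf(paste0("<hp_model: image %d, p=%d, d=%d, %d blocks, %d heads, ",
                     "L=%d; %s parameters>\n"),
              x$config$image_size, x$config$patch_size, x$config$embed_dim,
              x$config$n_blocks, x$config$n_heads, x$config$L,
              format(parameter_count(x$config), big.mark = ",")))
  invisible(x)
}

#' Trainable parameter count for a configuration
#'
#' Closed-form count over both branches; exactly matches the number of
#' scalars in an [init_model()] weight set.
#'
#' @param config `hp_model_config`.
#' @param n_branches number of branches (default 2).
#' @return integer parameter count.
#' @export
parameter_count <- function(config, n_branches = 2L) {
  d <- config$embed_dim; p <- config$patch_size; e <- config$ffn_expansion
  patch <- (4 * 64 + 64) + (4 * 64 * 64 + 64) + ((p %/% 4)^2 * 64 * d + d)
  pos <- config$N * d
  ln <- if (config$use_layernorm) 2 * (2 * d) else 0
  attn <- 4 * (d * d + d)
  ffn <- (d * e * d + e * d) + (9 * e * d + e * d) + (e * d * d + d)
  n_branches * (patch + pos + config$n_blocks * (ln + attn + ffn))
}

# resolve model/weights arguments
as_model <- function(model) {
  stopifnot(inherits(model, "hp_model"))
  model
}

#' Embed image patches for one branch
#'
#' Applies the branch's patch CNN to every p x p patch and adds its learned
#' position embedding.
#'
#' @param img `hp_image` or matrix matching the configured size.
#' @param branch `"histology"` or `"mr"`.
#' @param model `hp_model`.
#' @param add_pos add the position embedding (default `TRUE`).
#' @return N x d matrix with attributes `branch` and `stage = "embedded"`,
#'   rows in row-major patch order.
#' @export
embed_patches <- function(img, branch, model, add_pos = TRUE) {
  model <- as_model(model)
  cfg <- model$config
  px <- as_pixels(img)
  if (nrow(px) != cfg$image_size || ncol(px) != cfg$image_size) {
    stop(sprintf("embed_patches: image is %dx%d but config expects %d",
                 nrow(px), ncol(px), cfg$image_size))
  }
  geom <- model_geom(cfg)
  pw <- patch_weights(model$weights, branch)
  if (is.null(pw$W1)) stop("embed_patches: no weights for branch ", branch)
  out <- patch_f(px, pw, geom, add_pos = add_pos)$y
  structure(out, branch = branch, stage = "embedded")
}

#' Apply one locality-preserving encoder block
#'
#' Shape-preserving: multi-head self-attention with residual, then the
#' convolutional feed-forward (1x1 expand to 4d, 3x3 depthwise, 1x1 project)
#' on the sqrt(N) x sqrt(N) token grid, with residual.
#'
#' @param emb N x d embedding matrix.
#' @param model `hp_model`.
#' @param branch branch whose weights to use.
#' @param block block index (1-based).
#' @param attn_override `NULL`, or `"identity"` to force the attention
#'   matrix to the identity (diagnostic reductions only).
#' @param ffn_enabled set `FALSE` to zero out the feed-forward path
#'   (diagnostic reductions only).
#' @return N x d matrix.
#' @export
local_vit_block <- function(emb, model, branch, block = 1L,
                            attn_override = NULL, ffn_enabled = TRUE) {
  model <- as_model(model)
  cfg <- model$config
  if (nrow(emb) != cfg$N) stop("local_vit_block: token count != N")
  if (round(sqrt(nrow(emb)))^2 != nrow(emb)) {
    stop("local_vit_block: N must be a perfect square")
  }
  geom <- model_geom(cfg)
  bw <- block_weights(model$weights, branch, block)
  out <- block_f(unclass_mat(emb), bw, cfg$use_layernorm, cfg$n_heads,
                 geom$dwt, attn_override = attn_override,
                 ffn_enabled = ffn_enabled)$y
  structure(out, branch = branch, stage = attr(emb, "stage"))
}

unclass_mat <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

#' Encode patch embeddings with a branch's full block stack
#'
#' @param emb N x d embedded patch matrix (stage `"embedded"`).
#' @param model `hp_model`.
#' @param branch branch whose (unshared) weights to use; defaults to the
#'   embedding's `branch` attribute.
#' @inheritParams local_vit_block
#' @return N x d matrix with `stage = "encoded"`.
#' @export
encode <- function(emb, model, branch = NULL, attn_override = NULL,
                   ffn_enabled = TRUE) {
  model <- as_model(model)
  cfg <- model$config
  branch <- branch %||% attr(emb, "branch")
  if (is.null(branch)) stop("encode: branch not given and not on `emb`")
  x <- unclass_mat(emb)
  for (k in seq_len(cfg$n_blocks)) {
    x <- unclass_mat(local_vit_block(x, model, branch, k,
                                     attn_override = attn_override,
                                     ffn_enabled = ffn_enabled))
  }
  structure(x, branch = branch, stage = "encoded")
}

#' Gather encoded moving-image embeddings under each landmark
#'
#' Row i is the encoded embedding of the patch containing landmark i
#' (row-major patch index `floor(y/p) * sqrt(N) + floor(x/p)`). Invalid
#' landmarks gather patch 0 purely to keep shapes fixed; downstream masking
#' guarantees they never influence the output.
#'
#' @param enc_m encoded N x d moving-branch matrix.
#' @param X `hp_points` padded to L.
#' @param p patch size.
#' @return L x d matrix with attribute `valid`.
#' @export
gather_landmark_embeddings <- function(enc_m, X, p) {
  X <- as_points(X)
  g <- as.integer(round(sqrt(nrow(enc_m))))
  size <- g * p
  coords <- X$coords
  valid <- X$valid
  ok <- coords[, 1] >= 0 & coords[, 1] < size &
    coords[, 2] >= 0 & coords[, 2] < size
  if (any(valid & !ok)) {
    stop("gather_landmark_embeddings: landmark outside the image")
  }
  pidx <- rep(0, nrow(coords))
  pidx[valid] <- patch_index0(coords[valid, , drop = FALSE], p, g)
  structure(unclass_mat(enc_m)[pidx + 1, , drop = FALSE], valid = valid)
}

#' Landmark offsets from their patch centers
#'
#' `O = (X mod p) - floor(p/2)`, elementwise per axis; entries lie in
#' `[-floor(p/2), p - floor(p/2))`.
#'
#' @param X `hp_points` (padded).
#' @param p patch size.
#' @return L x 2 matrix of offsets in pixels.
#' @export
compute_offsets <- function(X, p) {
  X <- as_points(X)
  (X$coords %% p) - floor(p / 2)
}

#' Row-stochastic landmark-to-patch similarity
#'
#' Row-wise softmax over N of the L x N dot products between the gathered
#' moving embeddings and all encoded fixed embeddings. No scaling factor is
#' applied at the default temperature.
#'
#' @param Pm_prime L x d gathered moving embeddings.
#' @param enc_f N x d encoded fixed embeddings.
#' @param temperature softmax temperature (default 1).
#' @return L x N row-stochastic matrix.
#' @export
similarity <- function(Pm_prime, enc_f, temperature = 1) {
  if (ncol(Pm_prime) != ncol(enc_f)) {
    stop("similarity: embedding dimensions differ")
  }
  S <- softmax_rows(unclass_mat(Pm_prime) %*% t(unclass_mat(enc_f)) /
                      temperature)
  structure(S, valid = attr(Pm_prime, "valid"))
}

#' Soft-argmax over the patch-center meshgrid
#'
#' Expected (y, x) coordinate of each row of `S` under the meshgrid of patch
#' centers spanning `[p/2, image_size - p/2]` with spacing p, in the same
#' row-major order as the patch embeddings.
#'
#' @param S L x N row-stochastic similarity matrix.
#' @param p patch size.
#' @param image_size image side length.
#' @return L x 2 matrix of predicted coordinates (pre-offset).
#' @export
soft_argmax <- function(S, p, image_size) {
  g <- image_size %/% p
  if (ncol(S) != g * g) stop("soft_argmax: S has wrong number of columns")
  j0 <- 0:(ncol(S) - 1)
  centers <- cbind(p / 2 + p * (j0 %/% g), p / 2 + p * (j0 %% g))
  unclass_mat(S) %*% centers
}

#' Predict homologous points on the fixed image
#'
#' Full forward pass: embed and encode both branches (unshared weights),
#' gather the moving embeddings under the landmarks, compute offsets,
#' dot-product similarity, soft-argmax over patch centers, add the offsets,
#' and mask padding landmarks back to `(0, 0)`.
#'
#' @param M,F moving and fixed `hp_image`s at the configured size.
#' @param X `hp_points` padded to length L.
#' @param model `hp_model`.
#' @param moving_branch,fixed_branch which branch weights process each side
#'   (defaults histology/mr; mono-modal examples pass the same branch twice).
#' @return L x 2 matrix Y of predicted (y, x); invalid rows are exactly
#'   `(0, 0)`. The similarity matrix is attached as attribute
#'   `"similarity"`.
#' @export
predict_points <- function(M, F, X, model, moving_branch = "histology",
                           fixed_branch = "mr") {
  model <- as_model(model)
  cfg <- model$config
  X <- as_points(X)
  fw <- forward_pass(model$weights, cfg, as_pixels(M), as_pixels(F), X,
                     moving_branch, fixed_branch,
                     temperature = cfg$temperature)
  structure(fw$Y, similarity = fw$S, valid = fw$valid)
}

#' Similarity heatmap for one landmark (diagnostic)
#'
#' Reshapes one row of S onto the sqrt(N) x sqrt(N) patch grid (where it
#' sums to 1) and upsamples it to image resolution by pixel replication for
#' overlay on the fixed image.
#'
#' @param S L x N similarity matrix.
#' @param row landmark row index (1-based).
#' @param p patch size.
#' @param image_size image side length.
#' @return `hp_image` of the upsampled map, with the raw patch-grid matrix
#'   attached as attribute `"grid"`.
#' @export
similarity_heatmap <- function(S, row, p, image_size) {
  if (row < 1 || row > nrow(S)) stop("similarity_heatmap: invalid row")
  g <- image_size %/% p
  grid <- matrix(unclass_mat(S)[row, ], g, g, byrow = TRUE)
  up <- kronecker(grid, matrix(1, p, p))
  out <- hp_image(up / max(up), "mr")
  attr(out, "grid") <- grid
  out
}

#' Save a model checkpoint
#'
#' Single-file archive holding every named parameter tensor plus the
#' configuration serialized as JSON.
#'
#' @param model `hp_model`.
#' @param path output path (.rds).
#' @export
save_model <- function(model, path) {
  model <- as_model(model)
  saveRDS(list(config_json = jsonlite::toJSON(unclass(model$config),
                                              auto_unbox = TRUE),
               weights = model$weights,
               branches = model$branches),
          path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' Rebuilds the configuration from its JSON record and verifies that every
#' tensor has the shape the configuration implies.
#'
#' @param path checkpoint path written by [save_model()].
#' @return `hp_model`.
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  cj <- jsonlite::fromJSON(obj$config_json)
  cfg <- model_config(cj$image_size, cj$patch_size, cj$embed_dim, cj$n_blocks,
                      cj$n_heads, cj$L, cj$ffn_expansion, cj$use_layernorm,
                      cj$temperature)
  model <- structure(list(config = cfg, weights = obj$weights,
                          branches = obj$branches), class = "hp_model")
  ref <- init_model(cfg, seed = 1L, branches = obj$branches)
  for (nm in names(ref$weights)) {
    a <- dim(ref$weights[[nm]]) %||% length(ref$weights[[nm]])
    b <- dim(model$weights[[nm]]) %||% length(model$weights[[nm]])
    if (is.null(model$weights[[nm]]) || !identical(a, b)) {
      stop("load_model: checkpoint tensor '", nm,
           "' missing or shaped inconsistently with its config")
    }
  }
  model
}
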