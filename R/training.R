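# Training harness: TPS and rotation augmentation, the 50% same-modality
# branch-switching schema, the masked mean-absolute-error loss, and the Adam
# optimization loop over the hand-written backward pass.

#' Augmentation parameters
#'
#' @param tps_max_dev maximum per-axis control-point displacement of the
#'   random TPS deformation, pixels (default 16).
#' @param rotation_range rotation range in degrees, applied to the fixed
#'   image only (default 20, i.e. uniform on \[-20, 20\]).
#' @param grid_n control grid side (default 4, a 4 x 4 grid).
#' @return list of class `hp_aug_params`.
#' @export
aug_params <- function(tps_max_dev = 16, rotation_range = 20, grid_n = 4L) {
  stopifnot(tps_max_dev >= 0, rotation_range >= 0, grid_n >= 2)
  structure(list(tps_max_dev = tps_max_dev, rotation_range = rotation_range,
                 grid_n = grid_n), class = "hp_aug_params")
}

# invert a smooth near-identity map g (output -> input) at target points:
# find q with g(q) = p by fixed-point iteration.
invert_map_at <- function(g_fn, p, iters = 60, tol = 1e-10) {
  q <- p
  for (it in seq_len(iters)) {
    r <- g_fn(q) - p
    q <- q - r
    if (max(abs(r)) < tol) break
  }
  q
}

#' Random thin-plate-spline augmentation
#'
#' A `grid_n` x `grid_n` control grid spanning the frame is displaced by
#' i.i.d. uniform per-axis offsets in `[-tps_max_dev, tps_max_dev]`. The
#' displaced grid defines the backward (output-to-input) map; the image is
#' backward-warped through it exactly, and the points are carried forward by
#' inverting the same map (fixed-point iteration, sub-1e-8 px), so labels
#' stay on their image features.
#'
#' @param img `hp_image` (square).
#' @param pts `hp_points` in the image frame.
#' @param params `hp_aug_params`.
#' @param seed optional integer seed; `NULL` draws from the current RNG.
#' @return list with `image`, `points`, and the backward `transform`
#'   (`hp_tps`).
#' @export
random_tps_augment <- function(img, pts, params = aug_params(), seed = NULL) {
  px <- as_pixels(img)
  S <- nrow(px)
  pts <- as_points(pts)
  m <- params$tps_max_dev
  if (m == 0) {
    return(list(image = hp_image(px, img_modality(img)), points = pts,
                transform = identity_tps()))
  }
  gp <- as.matrix(expand.grid(y = seq(0, S, length.out = params$grid_n),
                              x = seq(0, S, length.out = params$grid_n)))
  offs <- with_seed(seed, matrix(stats::runif(nrow(gp) * 2, -m, m),
                                 ncol = 2))
  back <- fit_tps(gp, gp + offs)  # maps output coords -> source coords
  fill <- stats::median(c(px[1, ], px[S, ], px[, 1], px[, S]))
  out <- warp_backward(px, function(q) tps_eval(back, q), S, S, fill = fill)
  coords <- pts$coords
  if (any(pts$valid)) {
    coords[pts$valid, ] <-
      invert_map_at(function(q) tps_eval(back, q),
                    coords[pts$valid, , drop = FALSE])
  }
  list(image = hp_image(clamp(out, 0, 1), img_modality(img)),
       points = hp_points(coords, valid = pts$valid, class = pts$class),
       transform = back)
}

#' Random rotation augmentation (fixed side only)
#'
#' Rotates the image and its points about the frame center by an angle drawn
#' uniformly from `[-rotation_range, rotation_range]` degrees. The point
#' convention is `p' - c = [[cos, sin], [-sin, cos]] (p - c)` on (y, x).
#'
#' @param img `hp_image` (square).
#' @param pts `hp_points`.
#' @param params `hp_aug_params`.
#' @param seed optional seed.
#' @param theta force a specific angle in degrees (testing hook).
#' @return list with `image`, `points`, `theta`.
#' @export
random_rotation_augment <- function(img, pts, params = aug_params(),
                                    seed = NULL, theta = NULL) {
  px <- as_pixels(img)
  S <- nrow(px)
  pts <- as_points(pts)
  theta <- theta %||% with_seed(seed, stats::runif(1, -params$rotation_range,
                                                   params$rotation_range))
  th <- theta * pi / 180
  cth <- cos(th); sth <- sin(th)
  ctr <- c(S / 2, S / 2)
  Rm <- matrix(c(cth, -sth, sth, cth), 2, 2)  # forward map, rows (y, x)
  if (theta != 0) {
    fill <- stats::median(c(px[1, ], px[S, ], px[, 1], px[, S]))
    # backward map uses the inverse rotation
    Rb <- t(Rm)
    out <- warp_backward(px, function(q) {
      sweep(sweep(q, 2, ctr) %*% t(Rb), 2, ctr, "+")
    }, S, S, fill = fill)
  } else {
    out <- px
  }
  coords <- pts$coords
  if (any(pts$valid)) {
    coords[pts$valid, ] <-
      sweep(sweep(coords[pts$valid, , drop = FALSE], 2, ctr) %*% t(Rm),
            2, ctr, "+")
  }
  list(image = hp_image(clamp(out, 0, 1), img_modality(img)),
       points = hp_points(coords, valid = pts$valid, class = pts$class),
       theta = theta)
}

#' Sample one training example under the branch-switching schema
#'
#' With probability `same_modality_fraction`, both sides are independently
#' augmented copies of a single slide of one modality (chosen uniformly) and
#' the example trains that modality's branch on both sides; otherwise the
#' moving side is the slide's histology image and the fixed side its paired
#' MR image. Ground-truth output points are the annotation mapped through
#' the fixed-side augmentation. Rotation augmentation applies to the fixed
#' side only.
#'
#' @param dataset list of slides; each slide is a list with `histology`,
#'   `mr` (`hp_image`s), `hist_points`, `mr_points` (`hp_points`).
#' @param same_modality_fraction probability of a mono-modal example
#'   (default 0.5).
#' @param params `hp_aug_params`.
#' @param L padded point-list length.
#' @param seed optional seed.
#' @param augment set `FALSE` to disable augmentation (evaluation).
#' @return list of class `hp_example`: `moving`, `fixed`, `X`, `Y_true`
#'   (padded to L), `moving_modality`, `fixed_modality`.
#' @export
sample_training_example <- function(dataset, same_modality_fraction = 0.5,
                                    params = aug_params(), L = 75L,
                                    seed = NULL, augment = TRUE) {
  if (length(dataset) == 0) stop("sample_training_example: empty dataset")
  with_seed(seed, {
    slide <- dataset[[sample.int(length(dataset), 1)]]
    mono <- stats::runif(1) < same_modality_fraction
    if (mono) {
      modality <- sample(c("histology", "mr"), 1)
      img <- slide[[modality]]
      ann <- if (modality == "histology") slide$hist_points else slide$mr_points
      mov_mod <- fix_mod <- modality
      mov_img <- img; mov_pts <- ann
      fix_img <- img; fix_pts <- ann
    } else {
      mov_mod <- "histology"; fix_mod <- "mr"
      mov_img <- slide$histology; mov_pts <- slide$hist_points
      fix_img <- slide$mr; fix_pts <- slide$mr_points
    }
    if (augment) {
      ma <- random_tps_augment(mov_img, mov_pts, params)
      fa <- random_tps_augment(fix_img, fix_pts, params)
      fr <- random_rotation_augment(fa$image, fa$points, params)
      mov_img <- ma$image; mov_pts <- ma$points
      fix_img <- fr$image; fix_pts <- fr$points
    }
    # points pushed out of frame by augmentation are dropped from both sides
    S <- nrow(as_pixels(mov_img))
    ok <- mov_pts$valid & fix_pts$valid &
      mov_pts$coords[, 1] >= 0 & mov_pts$coords[, 1] < S &
      mov_pts$coords[, 2] >= 0 & mov_pts$coords[, 2] < S &
      fix_pts$coords[, 1] >= 0 & fix_pts$coords[, 1] < S &
      fix_pts$coords[, 2] >= 0 & fix_pts$coords[, 2] < S
    X <- pad_points(hp_points(mov_pts$coords[ok, , drop = FALSE]), L)
    Y <- pad_points(hp_points(fix_pts$coords[ok, , drop = FALSE]), L)
    structure(list(moving = mov_img, fixed = fix_img, X = X, Y_true = Y,
                   moving_modality = mov_mod, fixed_modality = fix_mod),
              class = "hp_example")
  })
}

#' Masked mean absolute error between predicted and true points
#'
#' Mean of the absolute coordinate errors (both axes pooled) over valid
#' points only; padding rows never contribute. Zero valid points yields 0
#' with a warning.
#'
#' @param Y_pred L x 2 matrix of predictions.
#' @param Y_true `hp_points` (padded) or L x 2 matrix.
#' @param valid optional explicit mask; must agree with `Y_true`'s mask if
#'   both are present.
#' @return scalar loss in pixels.
#' @export
masked_mae_loss <- function(Y_pred, Y_true, valid = NULL) {
  tp <- as_points(Y_true)
  pv <- attr(Y_pred, "valid")
  mask <- valid %||% tp$valid
  if (!is.null(valid) && length(tp$valid) == length(valid) &&
      !all(valid == tp$valid)) {
    stop("masked_mae_loss: validity masks disagree")
  }
  if (!is.null(pv) && !all(pv == mask)) {
    stop("masked_mae_loss: prediction and ground-truth masks disagree")
  }
  if (!any(mask)) {
    warning("masked_mae_loss: no valid points; loss defined as 0")
    return(0)
  }
  mean(abs(unclass_mat(Y_pred)[mask, , drop = FALSE] -
             tp$coords[mask, , drop = FALSE]))
}

# loss gradient wrt Y_pred (L x 2)
masked_mae_grad <- function(Y_pred, Y_true_coords, mask) {
  d <- matrix(0, nrow(Y_pred), 2)
  nv <- sum(mask)
  if (nv == 0) return(d)
  d[mask, ] <- sign(Y_pred[mask, , drop = FALSE] -
                      Y_true_coords[mask, , drop = FALSE]) / (2 * nv)
  d
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(weights) {
  list(m = lapply(weights, function(w) w * 0),
       v = lapply(weights, function(w) w * 0),
       t = 0L)
}

adam_step <- function(weights, grads, state, lr = 1e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(weights)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    weights[[nm]] <- weights[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(weights = weights, state = state)
}

# forward + loss + gradient for one example; returns loss and gradient env
example_grad <- function(weights, cfg, ex, G) {
  fw <- forward_pass(weights, cfg, as_pixels(ex$moving), as_pixels(ex$fixed),
                     ex$X, ex$moving_modality, ex$fixed_modality,
                     temperature = cfg$temperature)
  mask <- ex$X$valid & ex$Y_true$valid
  loss <- if (any(mask)) {
    mean(abs(fw$Y[mask, , drop = FALSE] - ex$Y_true$coords[mask, , drop = FALSE]))
  } else 0
  dY <- masked_mae_grad(fw$Y, ex$Y_true$coords, mask)
  backward_pass(fw, dY, weights, cfg, G)
  loss
}

#' Train the homologous point network
#'
#' Iterates the branch-switching example sampler, accumulates gradients of
#' the masked MAE loss over mini-batches with the package's hand-written
#' backward pass, and updates with Adam. Fully reproducible under a fixed
#' seed. When a validation set is given, the weights with the best
#' validation loss are retained alongside the final weights.
#'
#' @param dataset training slides (see [sample_training_example()]).
#' @param config `hp_model_config`.
#' @param epochs passes over the dataset (default 128); one epoch draws
#'   `length(dataset)` examples.
#' @param params `hp_aug_params`.
#' @param val_dataset optional validation slides (evaluated cross-modality,
#'   unaugmented).
#' @param lr,beta1,beta2,eps Adam settings (default lr 1e-4).
#' @param lr_schedule optional function(epoch) returning the learning rate
#'   for that epoch (overrides `lr`); `NULL` keeps it constant.
#' @param batch_size examples per update (default 4).
#' @param same_modality_fraction mono-modal example probability (default
#'   0.5).
#' @param seed integer seed for initialization and sampling.
#' @param init optional `hp_model` to continue training from.
#' @param verbose print per-epoch losses.
#' @return list with `model` (final), `best_model` (best validation loss, or
#'   final if no validation set), `history` (data.frame epoch / train_loss /
#'   val_loss) and `step_losses`.
#' @export
train <- function(dataset, config, epochs = 128L, params = aug_params(),
                  val_dataset = NULL, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                  eps = 1e-8, batch_size = 4L, same_modality_fraction = 0.5,
                  seed = 1L, init = NULL, lr_schedule = NULL,
                  verbose = FALSE) {
  if (length(dataset) < 1) stop("train: need at least one training slide")
  cfg <- config
  model <- init %||% init_model(cfg, seed = derive_seed(seed, 1L))
  weights <- model$weights
  state <- adam_init(weights)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  step_losses <- numeric(0)
  best <- list(loss = Inf, weights = weights)
  if (epochs > 0) {
    with_seed(derive_seed(seed, 2L), {
      for (ep in seq_len(epochs)) {
        lr_ep <- if (is.null(lr_schedule)) lr else lr_schedule(ep)
        ep_losses <- numeric(0)
        n_draw <- length(dataset)
        done <- 0
        while (done < n_draw) {
          nb <- min(batch_size, n_draw - done)
          G <- new.env(parent = emptyenv())
          bl <- numeric(nb)
          for (b in seq_len(nb)) {
            ex <- sample_training_example(dataset, same_modality_fraction,
                                          params, L = cfg$L)
            bl[b] <- example_grad(weights, cfg, ex, G)
          }
          if (any(!is.finite(bl))) {
            stop(sprintf("train: loss diverged (NaN/Inf) at epoch %d", ep))
          }
          grads <- grads_as_list(G, weights)
          grads <- lapply(grads, function(g) g / nb)
          upd <- adam_step(weights, grads, state, lr_ep, beta1, beta2, eps)
          weights <- upd$weights
          state <- upd$state
          ep_losses <- c(ep_losses, bl)
          done <- done + nb
        }
        step_losses <- c(step_losses, ep_losses)
        vl <- NA_real_
        if (!is.null(val_dataset)) {
          vl <- validation_loss(weights, cfg, val_dataset)
          if (vl < best$loss) best <- list(loss = vl, weights = weights)
        }
        history <- rbind(history,
                         data.frame(epoch = ep, train_loss = mean(ep_losses),
                                    val_loss = vl))
        if (verbose) {
          message(sprintf("epoch %3d  train %.3f  val %s", ep,
                          mean(ep_losses),
                          if (is.na(vl)) "-" else sprintf("%.3f", vl)))
        }
      }
    })
  }
  final <- structure(list(config = cfg, weights = weights,
                          branches = model$branches), class = "hp_model")
  best_model <- if (is.finite(best$loss)) {
    structure(list(config = cfg, weights = best$weights,
                   branches = model$branches), class = "hp_model")
  } else final
  list(model = final, best_model = best_model, history = history,
       step_losses = step_losses)
}

# cross-modality unaugmented loss over a dataset
validation_loss <- function(weights, cfg, dataset) {
  losses <- vapply(dataset, function(slide) {
    X <- pad_points(slide$hist_points, cfg$L)
    Y <- pad_points(slide$mr_points, cfg$L)
    fw <- forward_pass(weights, cfg, as_pixels(slide$histology),
                       as_pixels(slide$mr), X, "histology", "mr",
                       temperature = cfg$temperature)
    mask <- X$valid & Y$valid
    if (any(mask)) {
      mean(abs(fw$Y[mask, , drop = FALSE] - Y$coords[mask, , drop = FALSE]))
    } else 0
  }, numeric(1))
  mean(losses)
}
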