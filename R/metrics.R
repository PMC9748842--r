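# Registration evaluation: control point deviation, Dice coefficient, and
# whole-pipeline evaluation over a test set.  The two point-set roles are
# kept strictly separate: the detector/network correspondences drive the
# transform, the held-out ground-truth pairs score it.

#' Average control point deviation
#'
#' Mean Euclidean distance between the ground-truth moving-frame landmarks
#' mapped through the solved transform and their ground-truth fixed-frame
#' partners.
#'
#' @param t `hp_tps` (moving-to-fixed transform).
#' @param hist_gt ground-truth `hp_points` in moving (histology) space.
#' @param mr_gt paired ground-truth `hp_points` in fixed (MR) space.
#' @return mean deviation in pixels.
#' @export
control_point_deviation <- function(t, hist_gt, mr_gt) {
  hist_gt <- as_points(hist_gt); mr_gt <- as_points(mr_gt)
  if (nrow(hist_gt$coords) != nrow(mr_gt$coords)) {
    stop("control_point_deviation: point counts differ")
  }
  keep <- hist_gt$valid & mr_gt$valid
  if (!any(keep)) stop("control_point_deviation: zero valid point pairs")
  warped <- tps_eval(t, hist_gt$coords[keep, , drop = FALSE])
  mean(sqrt(rowSums((warped - mr_gt$coords[keep, , drop = FALSE])^2)))
}

#' Dice coefficient of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`. Two empty masks score 1 by default (perfect
#' vacuous agreement); set `empty = NA` for the undefined convention.
#'
#' @param mask_a,mask_b binary matrices of equal shape.
#' @param empty value returned when both masks are empty (default 1).
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b, empty = 1) {
  a <- as_pixels(mask_a) > 0.5
  b <- as_pixels(mask_b) > 0.5
  if (!all(dim(a) == dim(b))) stop("dice: mask shapes differ")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(empty)
  2 * sum(a & b) / (sa + sb)
}

#' Evaluate the full registration pipeline on a test set
#'
#' For each slide: select landmarks on the moving image, predict their
#' homologous fixed-space points with the network, fit a TPS on the
#' predicted correspondences, then score the transform with the held-out
#' ground-truth pairs (control point deviation) and, when masks are present,
#' Dice of the warped moving mask against the fixed mask. The ground-truth
#' pairs never enter the fit.
#'
#' @param testset list of slides (see [sample_training_example()] for the
#'   fields; masks optional).
#' @param model `hp_model`.
#' @param min_dist landmark minimum distance in pixels.
#' @param tps_lambda regularization used when fitting the predicted (noisy)
#'   correspondences (default 1).
#' @param max_points landmark cap (defaults to the model's L).
#' @param transform_fn optional override: a function(slide) returning an
#'   `hp_tps`, replacing the landmark+network+fit stages (oracle/baseline
#'   evaluations).
#' @return list with `per_slide` (data.frame: slide, n_landmarks,
#'   deviation_px, dice, dice_unregistered) and `summary` (means and sds).
#' @export
evaluate_pipeline <- function(testset, model = NULL, min_dist = 30,
                              tps_lambda = 1, max_points = NULL,
                              transform_fn = NULL) {
  rows <- list()
  for (si in seq_along(testset)) {
    slide <- testset[[si]]
    if (is.null(slide$hist_points) || is.null(slide$mr_points)) {
      message("evaluate_pipeline: slide ", si, " has no ground truth; skipped")
      next
    }
    nl <- NA_integer_
    if (is.null(transform_fn)) {
      cfg <- model$config
      X <- select_landmarks(slide$histology, min_dist = min_dist,
                            max_points = max_points %||% cfg$L)
      nl <- n_valid(X)
      Xp <- pad_points(X, cfg$L)
      Y <- predict_points(slide$histology, slide$mr, Xp, model)
      keep <- Xp$valid
      t_fit <- fit_tps(Xp$coords[keep, , drop = FALSE],
                       unclass_mat(Y)[keep, , drop = FALSE],
                       lambda = tps_lambda)
      src <- hp_points(Xp$coords[keep, , drop = FALSE])
      dst <- hp_points(unclass_mat(Y)[keep, , drop = FALSE])
    } else {
      t_fit <- transform_fn(slide)
      src <- dst <- NULL
    }
    dev <- control_point_deviation(t_fit, slide$hist_points, slide$mr_points)
    dc <- NA_real_; dc0 <- NA_real_
    if (!is.null(slide$hist_mask) && !is.null(slide$mr_mask)) {
      warped <- if (is.null(transform_fn)) {
        warp_image(slide$hist_mask, src, dst, lambda = tps_lambda)
      } else {
        # generic backward warp through the provided transform's inverse is
        # not available; warp via dense TPS resampling of the forward map
        warp_mask_through(slide$hist_mask, t_fit)
      }
      dc <- dice(as_pixels(warped) > 0.5, slide$mr_mask)
      dc0 <- dice(slide$hist_mask, slide$mr_mask)
    }
    rows[[length(rows) + 1]] <- data.frame(
      slide = slide$id %||% si, n_landmarks = nl, deviation_px = dev,
      dice = dc, dice_unregistered = dc0)
  }
  per_slide <- do.call(rbind, rows)
  list(per_slide = per_slide,
       summary = list(deviation_mean = mean(per_slide$deviation_px),
                      deviation_sd = stats::sd(per_slide$deviation_px),
                      dice_mean = mean(per_slide$dice),
                      dice_sd = stats::sd(per_slide$dice)))
}

# warp a moving-frame mask into fixed frame through a forward transform by
# inverting it pointwise on the pixel grid (used for oracle transforms)
warp_mask_through <- function(mask, t_fwd) {
  px <- as_pixels(mask)
  S <- nrow(px)
  out <- warp_backward(px, function(q) {
    invert_map_at(function(z) tps_eval(t_fwd, z), q, iters = 30, tol = 1e-6)
  }, S, S, fill = 0)
  hp_image(out, "histology")
}
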