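# Thin-plate-spline transform: fit from paired point sets, map points, warp
# images.  Classic formulation with kernel U(r) = r^2 log r and the bordered
# linear system; lambda adds Tikhonov smoothing on the kernel diagonal
# (lambda = 0 gives exact interpolation).

tps_kernel <- function(r) {
  out <- r * 0
  pos <- r > 0
  out[pos] <- r[pos]^2 * log(r[pos])
  out
}

pairwise_dist <- function(a, b) {
  # a: m x 2, b: k x 2 -> m x k Euclidean distances
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Fit a thin-plate-spline transform from paired points
#'
#' Solves the bordered linear system for an affine part plus radial-basis
#' weights per output axis. With `lambda = 0` the map interpolates every
#' source point onto its target exactly (points in general position);
#' `lambda > 0` trades interpolation error for smoothness.
#'
#' @param source `hp_points` or k x 2 matrix of source (y, x) points.
#' @param target `hp_points` or k x 2 matrix of target points; invalid rows
#'   (and their partners) are excluded.
#' @param lambda regularization added to the kernel diagonal (default 0).
#' @return object of class `hp_tps` with fields `source_points` (k x 2),
#'   `affine` (3 x 2: intercept, y, x coefficients per output axis),
#'   `weights` (k x 2) and `lambda`.
#' @export
fit_tps <- function(source, target, lambda = 0) {
  source <- as_points(source); target <- as_points(target)
  if (nrow(source$coords) != nrow(target$coords)) {
    stop("fit_tps: source and target must have equal point counts")
  }
  keep <- source$valid & target$valid
  s <- source$coords[keep, , drop = FALSE]
  t <- target$coords[keep, , drop = FALSE]
  k <- nrow(s)
  if (k < 3) stop("fit_tps: need at least 3 valid point pairs")
  D <- pairwise_dist(s, s)
  dup <- which(D + diag(Inf, k) < 1e-9, arr.ind = TRUE)
  if (lambda == 0 && nrow(dup) > 0) {
    stop(sprintf("fit_tps: duplicate source points at rows %d and %d",
                 dup[1, 1], dup[1, 2]))
  }
  P <- cbind(1, s)
  if (qr(P)$rank < 3) {
    stop("fit_tps: source points are collinear (rows ",
         paste(utils::head(which(keep), 5), collapse = ", "),
         " ...); cannot fit a TPS with lambda = 0")
  }
  K <- tps_kernel(D) + diag(lambda, k)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- rbind(t, matrix(0, 3, 2))
  sol <- tryCatch(solve(A, rhs),
                  error = function(e) stop("fit_tps: singular system (",
                                           conditionMessage(e), ")"))
  structure(list(source_points = s,
                 affine = sol[(k + 1):(k + 3), , drop = FALSE],
                 weights = sol[1:k, , drop = FALSE],
                 lambda = lambda),
            class = "hp_tps")
}

#' @export
print.hp_tps <- function(x, ...) {
  cat(sprintf("<hp_tps: %d control points, lambda=%g, bending energy=%.4g>\n",
              nrow(x$source_points), x$lambda, bending_energy(x)))
  invisible(x)
}

# Evaluate the transform at an m x 2 coordinate matrix.
tps_eval <- function(t, coords) {
  coords <- rbind(coords)
  .tps_eval(coords, t$source_points, t$affine, t$weights)
}

#' Identity transform helper
#' @return an `hp_tps` that maps every point to itself.
#' @export
identity_tps <- function() {
  structure(list(source_points = matrix(c(0, 0, 0, 1, 1, 0), 3, 2, byrow = TRUE),
                 affine = rbind(c(0, 0), c(1, 0), c(0, 1)),
                 weights = matrix(0, 3, 2),
                 lambda = 0),
            class = "hp_tps")
}

#' Map a point set through a fitted TPS
#'
#' @param t `hp_tps`.
#' @param pts `hp_points` or m x 2 matrix. Invalid rows pass through
#'   unchanged and stay invalid.
#' @return `hp_points`.
#' @export
transform_points <- function(t, pts) {
  pts <- as_points(pts)
  coords <- pts$coords
  if (any(pts$valid)) {
    coords[pts$valid, ] <- tps_eval(t, coords[pts$valid, , drop = FALSE])
  }
  hp_points(coords, valid = pts$valid, class = pts$class)
}

#' Bending energy of a fitted TPS
#'
#' Non-negative; zero iff the fitted map is purely affine.
#'
#' @param t `hp_tps`.
#' @return scalar bending energy (summed over the two output axes).
#' @export
bending_energy <- function(t) {
  K <- tps_kernel(pairwise_dist(t$source_points, t$source_points))
  sum(diag(crossprod(t$weights, K %*% t$weights)))
}

#' Warp a moving image into fixed-image space via paired points
#'
#' Fits the backward TPS (fixed-space -> moving-space, i.e. `mr_pts ->
#' hist_pts`) and samples the moving image at the mapped location of every
#' output pixel with bilinear interpolation; out-of-bounds samples fill
#' with `fill`.
#'
#' @param moving `hp_image` (or matrix) to warp.
#' @param hist_pts,mr_pts paired `hp_points` in moving/fixed space.
#' @param out_size output side length (defaults to the moving image size).
#' @param lambda TPS regularization (default 0).
#' @param fill out-of-bounds fill value (default 0).
#' @return warped `hp_image`.
#' @export
warp_image <- function(moving, hist_pts, mr_pts, out_size = NULL, lambda = 0,
                       fill = 0) {
  px <- as_pixels(moving)
  out_size <- out_size %||% nrow(px)
  t_back <- fit_tps(mr_pts, hist_pts, lambda = lambda)
  out <- warp_backward(px, function(q) tps_eval(t_back, q),
                       out_size, out_size, fill = fill)
  hp_image(clamp(out, 0, 1), img_modality(moving))
}

#' Serialize a TPS transform to JSON
#' @param t `hp_tps`.
#' @param path output path.
#' @export
write_tps <- function(t, path) {
  jsonlite::write_json(list(source_points = t$source_points,
                            affine = t$affine,
                            weights = t$weights,
                            lambda = t$lambda),
                       path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' Read a TPS transform from JSON
#' @param path JSON path written by [write_tps()].
#' @return `hp_tps`.
#' @export
read_tps <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(source_points = matrix(obj$source_points, ncol = 2),
                 affine = matrix(obj$affine, ncol = 2),
                 weights = matrix(obj$weights, ncol = 2),
                 lambda = obj$lambda),
            class = "hp_tps")
}
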