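# Landmark generation on the moving (histology) image: difference-of-Gaussians
# scale-space candidates, contrast filtering, Hessian-ratio edge scoring,
# edge/interior classification, and priority-aware minimum-distance thinning.
#
# Pyramid defaults follow Lowe's detector: 3 scales per octave, sigma0 = 1.6,
# octaves until the smaller image dimension drops below 16.  Blurring uses
# banded-matrix convolution with replicate boundaries (no FFT wraparound, so
# no spurious extrema at the frame).

gaussian_conv_matrix <- function(n, sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  M <- matrix(0, n, n)
  i <- seq_len(n)
  for (o in -r:r) {
    j <- clamp(i + o, 1L, n)
    M[cbind(i, j)] <- M[cbind(i, j)] + k[o + r + 1]
  }
  M
}

# Separable Gaussian blur with replicate boundary handling.
gaussian_blur <- function(px, sigma) {
  if (sigma <= 0) return(px)
  Gy <- gaussian_conv_matrix(nrow(px), sigma)
  Gx <- gaussian_conv_matrix(ncol(px), sigma)
  Gy %*% px %*% t(Gx)
}

# Build the Gaussian/DoG scale-space pyramid.
# Returns a list of octaves; each octave holds `gauss` (s + 3 images),
# `dog` (s + 2 images) and the octave scale factor 2^o.
build_dog_pyramid <- function(px, n_octaves = NULL, scales_per_octave = 3L,
                              sigma0 = 1.6, assumed_blur = 0.5) {
  s <- scales_per_octave
  max_oct <- max(0L, floor(log2(min(dim(px)) / 16)))
  n_oct <- min(n_octaves %||% (max_oct + 1L), max_oct + 1L)
  base <- gaussian_blur(px, sqrt(max(sigma0^2 - assumed_blur^2, 0.01)))
  k <- 2^(1 / s)
  # incremental blur increments between successive scale levels
  sig_inc <- sigma0 * sqrt(k^(2 * seq_len(s + 2)) - k^(2 * (seq_len(s + 2) - 1)))
  octaves <- vector("list", n_oct)
  for (o in seq_len(n_oct)) {
    gauss <- vector("list", s + 3)
    gauss[[1]] <- base
    for (l in seq_len(s + 2)) {
      gauss[[l + 1]] <- gaussian_blur(gauss[[l]], sig_inc[l])
    }
    dog <- lapply(seq_len(s + 2), function(l) gauss[[l + 1]] - gauss[[l]])
    octaves[[o]] <- list(gauss = gauss, dog = dog, factor = 2^(o - 1))
    if (o < n_oct) {
      down <- gauss[[s + 1]]  # blur 2 * sigma0 level
      base <- down[seq(1, nrow(down), by = 2), seq(1, ncol(down), by = 2),
                   drop = FALSE]
    }
  }
  octaves
}

#' Edge score from the 2-D spatial Hessian of the DoG
#'
#' `Tr(H)^2 / Det(H)`, a monotone surrogate of the larger/smaller Hessian
#' eigenvalue ratio for `Det > 0`; its minimum is 4 at equal eigenvalues.
#' Candidates with non-positive determinant (saddles) score `Inf`.
#'
#' @param dyy,dxx,dxy second-order finite differences of the DoG.
#' @return numeric edge score(s).
#' @export
hessian_edge_score <- function(dyy, dxx, dxy) {
  tr <- dyy + dxx
  det <- dyy * dxx - dxy^2
  ifelse(det > 0, tr^2 / det, Inf)
}

# 26-neighborhood strict extrema of a DoG octave.  Returns integer matrix
# (row, col, level) of interior extrema.
dog_extrema <- function(dog) {
  nl <- length(dog)
  H <- nrow(dog[[1]]); W <- ncol(dog[[1]])
  if (H < 3 || W < 3) return(matrix(integer(0), 0, 3))
  out <- list()
  ry <- 2:(H - 1); rx <- 2:(W - 1)
  for (l in 2:(nl - 1)) {
    C <- dog[[l]][ry, rx]
    ismax <- matrix(TRUE, length(ry), length(rx))
    ismin <- ismax
    for (dl in -1:1) {
      D <- dog[[l + dl]]
      for (dy in -1:1) for (dx in -1:1) {
        if (dl == 0 && dy == 0 && dx == 0) next
        Nb <- D[ry + dy, rx + dx]
        ismax <- ismax & (C > Nb)
        ismin <- ismin & (C < Nb)
      }
    }
    # a magnitude floor keeps float dust on flat regions from registering
    hit <- which((ismax | ismin) & abs(C) > 1e-8, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      out[[length(out) + 1]] <- cbind(hit[, 1] + 1L, hit[, 2] + 1L, l)
    }
  }
  if (length(out) == 0) matrix(integer(0), 0, 3) else do.call(rbind, out)
}

#' Detect DoG scale-space keypoint candidates
#'
#' Candidates are strict extrema of the DoG pyramid over their 3 x 3 x 3
#' neighborhood. The contrast score is `|D|` at the (optionally sub-pixel
#' refined) candidate, measured on the `[0, 1]`-scaled image; an edge score
#' (see [hessian_edge_score()]) is computed at the same location.
#'
#' @param img normalized `hp_image` (or matrix in `[0, 1]`).
#' @param n_octaves number of octaves (default: until min dimension < 16).
#' @param scales_per_octave scales per octave (default 3).
#' @param sigma0 base blur of the first level (default 1.6).
#' @param refine quadratic sub-pixel refinement of position and contrast
#'   (default `TRUE`); with `FALSE` the raw `|D|` at the grid extremum is
#'   used.
#' @return data.frame with columns `y`, `x` (full-resolution pixel-center
#'   coordinates), `octave`, `level`, `contrast`, `edge_score`; the DoG
#'   pyramid is attached as attribute `"pyramid"`.
#' @export
detect_candidates <- function(img, n_octaves = NULL, scales_per_octave = 3L,
                              sigma0 = 1.6, refine = TRUE) {
  px <- as_pixels(img)
  if (min(dim(px)) < 16) {
    stop("detect_candidates: image smaller than one octave (min dim < 16)")
  }
  pyr <- build_dog_pyramid(px, n_octaves, scales_per_octave, sigma0)
  rows <- list()
  for (o in seq_along(pyr)) {
    dog <- pyr[[o]]$dog
    ext <- dog_extrema(dog)
    if (nrow(ext) == 0) next
    n <- nrow(ext)
    ys <- numeric(n); xs <- numeric(n); con <- numeric(n); esc <- numeric(n)
    for (i in seq_len(n)) {
      r <- ext[i, 1]; c <- ext[i, 2]; l <- ext[i, 3]
      D0 <- dog[[l]]
      val <- D0[r, c]
      dyy <- D0[r + 1, c] + D0[r - 1, c] - 2 * val
      dxx <- D0[r, c + 1] + D0[r, c - 1] - 2 * val
      dxy <- (D0[r + 1, c + 1] - D0[r + 1, c - 1] -
              D0[r - 1, c + 1] + D0[r - 1, c - 1]) / 4
      esc[i] <- hessian_edge_score(dyy, dxx, dxy)
      off <- c(0, 0, 0)
      contrast <- abs(val)
      if (refine) {
        Dm <- dog[[l - 1]]; Dp <- dog[[l + 1]]
        g <- c((D0[r + 1, c] - D0[r - 1, c]) / 2,
               (D0[r, c + 1] - D0[r, c - 1]) / 2,
               (Dp[r, c] - Dm[r, c]) / 2)
        dss <- Dp[r, c] + Dm[r, c] - 2 * val
        dys <- (Dp[r + 1, c] - Dp[r - 1, c] - Dm[r + 1, c] + Dm[r - 1, c]) / 4
        dxs <- (Dp[r, c + 1] - Dp[r, c - 1] - Dm[r, c + 1] + Dm[r, c - 1]) / 4
        Hm <- matrix(c(dyy, dxy, dys,
                       dxy, dxx, dxs,
                       dys, dxs, dss), 3, 3)
        off <- tryCatch(solve(Hm, -g), error = function(e) c(0, 0, 0))
        if (any(!is.finite(off)) || max(abs(off)) > 1.5) off <- c(0, 0, 0)
        off <- clamp(off, -0.5, 0.5)
        contrast <- abs(val + 0.5 * sum(g * off))
      }
      # 0-based pixel index within octave, then continuous full-res coords
      ys[i] <- (r - 1 + off[1] + 0.5) * pyr[[o]]$factor
      xs[i] <- (c - 1 + off[2] + 0.5) * pyr[[o]]$factor
      con[i] <- contrast
    }
    rows[[length(rows) + 1]] <-
      data.frame(y = ys, x = xs, octave = o - 1L, level = ext[, 3] - 1L,
                 contrast = con, edge_score = esc)
  }
  out <- if (length(rows) == 0) {
    data.frame(y = numeric(0), x = numeric(0), octave = integer(0),
               level = integer(0), contrast = numeric(0),
               edge_score = numeric(0))
  } else {
    do.call(rbind, rows)
  }
  attr(out, "pyramid") <- pyr
  out
}

#' Remove low-contrast candidates
#'
#' @param cands candidate data.frame from [detect_candidates()].
#' @param threshold minimum contrast on the `[0, 1]` intensity scale
#'   (default 0.04).
#' @return filtered data.frame, order preserved.
#' @export
filter_contrast <- function(cands, threshold = 0.04) {
  out <- cands[cands$contrast >= threshold, , drop = FALSE]
  attr(out, "pyramid") <- attr(cands, "pyramid")
  out
}

#' (Re)compute edge scores for candidates
#'
#' Normally [detect_candidates()] fills `edge_score` already; this operation
#' recomputes it from the image, rebuilding the pyramid if the candidates do
#' not carry one.
#'
#' @param img normalized image the candidates came from.
#' @param cands candidate data.frame.
#' @inheritParams detect_candidates
#' @return data.frame with `edge_score` set.
#' @export
score_edges <- function(img, cands, scales_per_octave = 3L, sigma0 = 1.6) {
  pyr <- attr(cands, "pyramid")
  if (is.null(pyr)) {
    pyr <- build_dog_pyramid(as_pixels(img), NULL, scales_per_octave, sigma0)
  }
  n <- nrow(cands)
  esc <- numeric(n)
  for (i in seq_len(n)) {
    o <- cands$octave[i] + 1L
    fac <- pyr[[o]]$factor
    D0 <- pyr[[o]]$dog[[cands$level[i] + 1L]]
    r <- clamp(round(cands$y[i] / fac - 0.5) + 1L, 2L, nrow(D0) - 1L)
    c <- clamp(round(cands$x[i] / fac - 0.5) + 1L, 2L, ncol(D0) - 1L)
    val <- D0[r, c]
    dyy <- D0[r + 1, c] + D0[r - 1, c] - 2 * val
    dxx <- D0[r, c + 1] + D0[r, c - 1] - 2 * val
    dxy <- (D0[r + 1, c + 1] - D0[r + 1, c - 1] -
            D0[r - 1, c + 1] + D0[r - 1, c - 1]) / 4
    esc[i] <- hessian_edge_score(dyy, dxx, dxy)
  }
  cands$edge_score <- esc
  attr(cands, "pyramid") <- pyr
  cands
}

#' Classify candidates into edge and interior points
#'
#' The `ceiling(edge_fraction * n)` candidates with the highest edge score
#' are labeled `"edge"`, the rest `"interior"`. Ties break by higher
#' contrast, then by scan order, so labeling is deterministic.
#'
#' @param cands candidate data.frame with `edge_score` populated.
#' @param edge_fraction fraction labeled edge (default 0.19, i.e. the top
#'   19% of candidates by edge score).
#' @return data.frame with a `class` column.
#' @export
classify_edges <- function(cands, edge_fraction = 0.19) {
  n <- nrow(cands)
  cls <- rep("interior", n)
  if (n > 0) {
    n_edge <- ceiling(edge_fraction * n)
    ord <- order(-cands$edge_score, -cands$contrast, seq_len(n))
    cls[ord[seq_len(n_edge)]] <- "edge"
  }
  cands$class <- cls
  attr(cands, "pyramid") <- attr(cands, "pyramid")
  cands
}

#' Enforce a minimum pairwise distance, prioritizing edge points
#'
#' Points are visited greedily — all edge points by descending contrast,
#' then interior points by descending contrast — and kept iff they lie at
#' least `min_dist` pixels from every already-kept point. An interior point
#' therefore always loses an edge/interior conflict.
#'
#' @param cands classified candidate data.frame.
#' @param min_dist minimum pairwise Euclidean distance in pixels.
#' @return `hp_points` with `class` set; per-point contrast is attached as
#'   attribute `"contrast"`.
#' @export
enforce_min_distance <- function(cands, min_dist) {
  if (!is.numeric(min_dist) || min_dist <= 0) {
    stop("enforce_min_distance: min_dist must be > 0")
  }
  n <- nrow(cands)
  if (n == 0) return(hp_points(NULL, class = character(0)))
  is_edge <- cands$class == "edge"
  ord <- c(which(is_edge)[order(-cands$contrast[is_edge])],
           which(!is_edge)[order(-cands$contrast[!is_edge])])
  kept <- integer(0)
  kc <- matrix(numeric(0), 0, 2)
  for (i in ord) {
    p <- c(cands$y[i], cands$x[i])
    if (nrow(kc) == 0 ||
        min(sqrt((kc[, 1] - p[1])^2 + (kc[, 2] - p[2])^2)) >= min_dist) {
      kept <- c(kept, i)
      kc <- rbind(kc, p)
    }
  }
  kept <- sort(kept)  # restore scan order
  out <- hp_points(cbind(cands$y[kept], cands$x[kept]),
                   class = cands$class[kept])
  attr(out, "contrast") <- cands$contrast[kept]
  out
}

#' Select landmarks on a histology image
#'
#' Full landmark generation: DoG candidate detection, contrast filtering at
#' `contrast_threshold`, edge scoring and classification, then
#' minimum-distance thinning. If more than `max_points` survive, the
#' lowest-contrast interior points are dropped first (then lowest-contrast
#' edges) so the set fits the network's point capacity.
#'
#' @param img normalized `hp_image`.
#' @param min_dist minimum pairwise distance in pixels (default 30 at
#'   512 x 512).
#' @param max_points cap on emitted points (default 75).
#' @param contrast_threshold DoG contrast cutoff (default 0.04).
#' @param edge_fraction fraction classified as edges (default 0.19).
#' @param ... passed to [detect_candidates()].
#' @return `hp_points` with `class`; contrast attached as attribute.
#' @export
select_landmarks <- function(img, min_dist = 30, max_points = 75,
                             contrast_threshold = 0.04, edge_fraction = 0.19,
                             ...) {
  cands <- detect_candidates(img, ...)
  cands <- filter_contrast(cands, contrast_threshold)
  cands <- score_edges(img, cands)
  cands <- classify_edges(cands, edge_fraction)
  pts <- enforce_min_distance(cands, min_dist)
  nv <- n_valid(pts)
  if (nv > max_points) {
    con <- attr(pts, "contrast")
    is_int <- pts$class == "interior"
    drop_rank <- order(!is_int, con)  # interiors first, lowest contrast first
    drop <- drop_rank[seq_len(nv - max_points)]
    keep <- setdiff(seq_len(nv), drop)
    out <- hp_points(pts$coords[keep, , drop = FALSE], class = pts$class[keep])
    attr(out, "contrast") <- con[keep]
    return(out)
  }
  pts
}
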