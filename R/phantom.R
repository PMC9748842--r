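# Synthetic phantom generator: modality-styled image pairs with known
# ground-truth homologous points, organ masks and a known nonlinear
# deformation, emulating the structure of whole-mount histology / T2 MR
# slide pairs (organ-scale blob, internal structures, dark stained contours
# on a bright field vs. a distinct intensity mapping with coarse noise).

# closed smooth curve: low-order Fourier perturbation of a circle
make_curve <- function(center, r0, n_harmonics = 3L, amp = 0.08) {
  k <- seq(2, 1 + n_harmonics)
  list(center = center, r0 = r0,
       a = stats::runif(n_harmonics, -amp, amp),
       phi = stats::runif(n_harmonics, 0, 2 * pi),
       k = k)
}

curve_radius <- function(curve, theta) {
  r <- rep(curve$r0, length(theta))
  for (i in seq_along(curve$k)) {
    r <- r + curve$r0 * curve$a[i] * cos(curve$k[i] * theta + curve$phi[i])
  }
  r
}

# signed distance surrogate (rho - radius(theta)): negative inside
curve_sd <- function(curve, ys, xs) {
  dy <- ys - curve$center[1]; dx <- xs - curve$center[2]
  rho <- sqrt(dy^2 + dx^2)
  rho - curve_radius(curve, atan2(dx, dy))
}

# signed distance plus polar angle (for along-contour modulation)
curve_sd_theta <- function(curve, ys, xs) {
  dy <- ys - curve$center[1]; dx <- xs - curve$center[2]
  rho <- sqrt(dy^2 + dx^2)
  theta <- atan2(dx, dy)
  list(sd = rho - curve_radius(curve, theta), theta = theta)
}

curve_point <- function(curve, theta, shrink = 1) {
  r <- curve_radius(curve, theta) * shrink
  cbind(curve$center[1] + r * cos(theta), curve$center[2] + r * sin(theta))
}

# gland-like dark dot features sitting on the stain-modulation maxima of a
# curve's contour; these blob-scale features are what a DoG detector keys on
# in stained tissue
curve_dots <- function(curve, spacing = 18) {
  f <- max(4, round(2 * pi * curve$r0 / spacing))
  th <- (2 * pi * seq_len(f) - curve$phi[1] * 7) / f
  curve_point(curve, th)
}

# render both modality styles from the geometry, evaluated at (ys, xs)
render_phantom <- function(geom, ys, xs, style, noise) {
  organ_sd <- curve_sd(geom$organ, ys, xs)
  inside <- organ_sd < 0
  if (style == "histology") {
    img <- rep(0.93, length(ys))
    img[inside] <- 0.72
    tints <- rep(c(0.50, 0.62, 0.56, 0.44, 0.66), length.out =
                   length(geom$structs))
    for (i in seq_along(geom$structs)) {
      sd <- curve_sd(geom$structs[[i]], ys, xs)
      img[sd < 0 & inside] <- tints[i]
    }
    usd <- curve_sd(geom$urethra, ys, xs)
    img[usd < 0 & inside] <- 0.25
    # dark stained contour lines along every boundary; stain density varies
    # along the contour (as H&E staining does), which is what gives the
    # scale-space detector isolated extrema on the lines
    for (cv in c(list(geom$organ), geom$structs, list(geom$urethra))) {
      st <- curve_sd_theta(cv, ys, xs)
      f <- max(4, round(2 * pi * cv$r0 / 18))
      depth <- 0.55 + 0.45 * cos(f * st$theta + cv$phi[1] * 7)
      img <- img * (1 - 0.55 * depth * exp(-(st$sd / 1.4)^2))
      for (j in seq_len(nrow(cv$dots))) {
        d2 <- (ys - cv$dots[j, 1])^2 + (xs - cv$dots[j, 2])^2
        img <- img * (1 - 0.62 * exp(-d2 / (2 * 2.2^2)))
      }
    }
    img <- img + noise * inside
  } else {
    img <- rep(0.08, length(ys))
    img[inside] <- 0.58
    tints <- rep(c(0.78, 0.38, 0.70, 0.45, 0.82), length.out =
                   length(geom$structs))
    for (i in seq_along(geom$structs)) {
      sd <- curve_sd(geom$structs[[i]], ys, xs)
      img[sd < 0 & inside] <- tints[i]
    }
    usd <- curve_sd(geom$urethra, ys, xs)
    img[usd < 0 & inside] <- 0.12
    # the same structural features under the MR intensity mapping: boundaries
    # and nodular foci are visible on T2, just dimmer and smoother than the
    # stained histology counterparts
    for (cv in c(list(geom$organ), geom$structs, list(geom$urethra))) {
      st <- curve_sd_theta(cv, ys, xs)
      f <- max(4, round(2 * pi * cv$r0 / 18))
      depth <- 0.55 + 0.45 * cos(f * st$theta + cv$phi[1] * 7)
      img <- img * (1 - 0.3 * depth * exp(-(st$sd / 1.6)^2))
      for (j in seq_len(nrow(cv$dots))) {
        d2 <- (ys - cv$dots[j, 1])^2 + (xs - cv$dots[j, 2])^2
        img <- img * (1 - 0.4 * exp(-d2 / (2 * 2.4^2)))
      }
    }
    img <- img + noise
  }
  clamp(img, 0, 1)
}

#' Generate a synthetic registration phantom
#'
#' Builds an organ-scale smooth blob with 2-5 internal structures and a
#' central urethra-like hole, renders it in a histology style (bright field,
#' fine-grain texture, dark boundary contours) as the moving image and in an
#' MR style (dark field, distinct tissue intensities, coarse noise, mild
#' blur) as the fixed image of the nonlinearly deformed geometry, and
#' samples paired ground-truth homologous points (half on the organ
#' boundary, half on internal structure contours).
#'
#' The deformation is a random thin-plate spline on a 4 x 4 control grid,
#' rescaled in closed form so that the mean ground-truth point displacement
#' equals `deformation_px` exactly.
#'
#' @param seed integer seed; same seed, same phantom, bit for bit.
#' @param size image side in pixels (default 512).
#' @param deformation_px mean ground-truth displacement of the moving-to-
#'   fixed deformation, pixels (default 12).
#' @param n_internal number of internal structures, 2-5 (default 3).
#' @param n_gt_points number of ground-truth homologous point pairs
#'   (default 24).
#' @param organ_radius_frac range of the organ base radius as a fraction of
#'   `size` (default 0.22-0.30).
#' @return object of class `hp_phantom`: `moving`, `fixed` (`hp_image`),
#'   `moving_mask`, `fixed_mask` (binary matrices), `gt_moving`, `gt_fixed`
#'   (`hp_points`), `true_deformation` (`hp_tps`, moving to fixed frame),
#'   `seed`.
#' @export
generate_phantom <- function(seed, size = 512L, deformation_px = 12,
                             n_internal = 3L, n_gt_points = 24L,
                             organ_radius_frac = c(0.22, 0.30)) {
  if (size < 32 || n_gt_points < 4 || n_internal < 2 || n_internal > 5 ||
      deformation_px < 0 || any(organ_radius_frac <= 0)) {
    stop("generate_phantom: infeasible parameters")
  }
  with_seed(derive_seed(seed, 101L), {
    ctr <- size / 2 + stats::runif(2, -0.03, 0.03) * size
    r0 <- stats::runif(1, organ_radius_frac[1], organ_radius_frac[2]) * size
    organ <- make_curve(ctr, r0)
    r_min <- r0 * (1 - sum(abs(organ$a)))
    structs <- vector("list", n_internal)
    for (i in seq_len(n_internal)) {
      psi <- stats::runif(1, 0, 2 * pi)
      rho <- stats::runif(1, 0.25, 0.55) * r0
      rs <- stats::runif(1, 0.16, 0.26) * r0
      # keep the structure well inside the organ
      max_rs <- 0.85 * r_min - rho
      rs <- min(rs, max(max_rs, 0.08 * r0))
      structs[[i]] <- make_curve(ctr + rho * c(cos(psi), sin(psi)), rs,
                                 amp = 0.1)
    }
    urethra <- make_curve(ctr + stats::runif(2, -0.08, 0.08) * r0,
                          0.1 * r0, amp = 0.05)
    organ$dots <- curve_dots(organ)
    structs <- lapply(structs, function(cv) { cv$dots <- curve_dots(cv); cv })
    urethra$dots <- curve_dots(urethra)
    geom <- list(organ = organ, structs = structs, urethra = urethra)

    # ground-truth homologous points: boundary half, internal-contour half
    nb <- ceiling(n_gt_points / 2)
    ni <- n_gt_points - nb
    th_b <- 2 * pi * (seq_len(nb) - 1) / nb + stats::runif(nb, -0.1, 0.1)
    gt <- curve_point(organ, th_b, shrink = 0.98)
    contours <- c(structs, list(urethra))
    th_i <- stats::runif(ni, 0, 2 * pi)
    for (j in seq_len(ni)) {
      cv <- contours[[1 + (j - 1) %% length(contours)]]
      gt <- rbind(gt, curve_point(cv, th_i[j]))
    }

    # deformation: random TPS, calibrated to the requested mean displacement
    if (deformation_px > 0) {
      gp <- as.matrix(expand.grid(y = seq(0.1, 0.9, length.out = 4) * size,
                                  x = seq(0.1, 0.9, length.out = 4) * size))
      offs <- matrix(stats::runif(nrow(gp) * 2, -deformation_px,
                                  deformation_px), ncol = 2)
      t0 <- fit_tps(gp, gp + offs)
      d0 <- mean(sqrt(rowSums((tps_eval(t0, gt) - gt)^2)))
      offs <- offs * deformation_px / d0  # TPS displacement is linear in offs
      deform <- fit_tps(gp, gp + offs)
      deform_inv <- fit_tps(gp + offs, gp)
    } else {
      deform <- identity_tps()
      deform_inv <- identity_tps()
    }

    # moving-frame render at pixel centers
    yy <- rep(seq_len(size) - 0.5, times = size)
    xx <- rep(seq_len(size) - 0.5, each = size)
    fine <- gaussian_blur(matrix(stats::runif(size^2, -0.06, 0.06),
                                 size, size), 0.7)
    mov <- matrix(render_phantom(geom, yy, xx, "histology",
                                 as.vector(fine)), size, size)
    mov <- gaussian_blur(mov, 0.4)
    mov_mask <- matrix(curve_sd(organ, yy, xx) < 0, size, size) * 1

    # fixed-frame render: evaluate geometry at the inverse-mapped coords
    src <- tps_eval(deform_inv, cbind(yy, xx))
    cg <- max(4L, size %/% 8L)
    coarse <- kronecker(matrix(stats::runif(cg^2, -0.05, 0.05), cg, cg),
                        matrix(1, ceiling(size / cg), ceiling(size / cg)))
    coarse <- coarse[seq_len(size), seq_len(size)]
    fix <- matrix(render_phantom(geom, src[, 1], src[, 2], "mr",
                                 as.vector(coarse)), size, size)
    fix <- gaussian_blur(fix, max(0.6, 1.2 * size / 512))
    fix_mask <- matrix(curve_sd(organ, src[, 1], src[, 2]) < 0, size, size) * 1

    gt_moving <- hp_points(gt)
    gt_fixed <- transform_points(deform, gt_moving)
    structure(list(moving = hp_image(clamp(mov, 0, 1), "histology"),
                   fixed = hp_image(clamp(fix, 0, 1), "mr"),
                   moving_mask = mov_mask, fixed_mask = fix_mask,
                   gt_moving = gt_moving, gt_fixed = gt_fixed,
                   true_deformation = deform, geometry = geom,
                   seed = seed, size = size),
              class = "hp_phantom")
  })
}

#' @export
print.hp_phantom <- function(x, ...) {
  d <- mean(sqrt(rowSums((x$gt_fixed$coords - x$gt_moving$coords)^2)))
  cat(sprintf("<hp_phantom: %dx%d, %d GT pairs, mean displacement %.2f px, seed %d>\n",
              x$size, x$size, nrow(x$gt_moving$coords), d, x$seed))
  invisible(x)
}

# distance from points to the nearest rendered contour (used by tests)
phantom_contour_distance <- function(ph, coords) {
  cvs <- c(list(ph$geometry$organ), ph$geometry$structs,
           list(ph$geometry$urethra))
  d <- matrix(Inf, nrow(coords), length(cvs))
  for (i in seq_along(cvs)) {
    d[, i] <- abs(curve_sd(cvs[[i]], coords[, 1], coords[, 2]))
  }
  apply(d, 1, min)
}

# phantom -> training/evaluation slide structure
phantom_to_slide <- function(ph) {
  list(histology = ph$moving, mr = ph$fixed,
       hist_points = ph$gt_moving, mr_points = ph$gt_fixed,
       hist_mask = ph$moving_mask, mr_mask = ph$fixed_mask,
       true_deformation = ph$true_deformation,
       id = sprintf("phantom_%d", ph$seed))
}

#' Generate an in-memory phantom dataset
#'
#' @param n number of phantoms.
#' @param seed parent seed; phantom i uses `derive_seed(seed, i)`.
#' @param ... passed to [generate_phantom()].
#' @return list of slides consumable by [train()] and
#'   [evaluate_pipeline()].
#' @export
phantom_dataset <- function(n, seed, ...) {
  lapply(seq_len(n), function(i) {
    phantom_to_slide(generate_phantom(derive_seed(seed, i), ...))
  })
}

#' Write a phantom corpus to disk
#'
#' Emits PNG images and masks, point CSVs and a JSON manifest with a
#' 70/15/15 train/validation/test split by phantom id. Regeneration with
#' the same seed is byte-identical.
#'
#' @param n number of phantoms (>= 1).
#' @param seed parent seed.
#' @param out_dir output directory (created if missing).
#' @param split train/val/test fractions (default 0.7/0.15/0.15).
#' @param ... passed to [generate_phantom()].
#' @return the manifest (invisibly), also written to
#'   `out_dir/manifest.json`.
#' @export
generate_corpus <- function(n, seed, out_dir, split = c(0.7, 0.15, 0.15),
                            ...) {
  stopifnot(n >= 1)
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("generate_corpus: cannot create ", out_dir)
  n_train <- floor(split[1] * n)
  n_val <- floor(split[2] * n)
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- generate_phantom(derive_seed(seed, i), ...)
    id <- sprintf("phantom_%03d", i)
    paths <- list(
      moving = file.path(out_dir, paste0(id, "_moving.png")),
      fixed = file.path(out_dir, paste0(id, "_fixed.png")),
      moving_mask = file.path(out_dir, paste0(id, "_moving_mask.png")),
      fixed_mask = file.path(out_dir, paste0(id, "_fixed_mask.png")),
      points_moving = file.path(out_dir, paste0(id, "_points_moving.csv")),
      points_fixed = file.path(out_dir, paste0(id, "_points_fixed.csv")))
    write_raster(ph$moving, paths$moving)
    write_raster(ph$fixed, paths$fixed)
    write_raster(ph$moving_mask, paths$moving_mask)
    write_raster(ph$fixed_mask, paths$fixed_mask)
    write_points(ph$gt_moving, paths$points_moving)
    write_points(ph$gt_fixed, paths$points_fixed)
    splt <- if (i <= n_train) "train" else if (i <= n_train + n_val) "val" else "test"
    entries[[i]] <- c(list(id = id, split = splt, seed = ph$seed),
                      lapply(paths, basename))
  }
  manifest <- list(n = n, seed = seed, entries = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Degrade a phantom with histology-style artifacts
#'
#' Stress-test generator for torn, folded or partial tissue sections.
#' Ground-truth points falling in destroyed regions are marked invalid.
#'
#' @param ph `hp_phantom`.
#' @param mode `"tear"` (crack removed from the boundary inward), `"fold"`
#'   (mirrored overlapped strip) or `"partial"` (crop removing `severity` of
#'   the mask area).
#' @param severity in `[0, 1]`; 0 returns the phantom unchanged.
#' @return degraded `hp_phantom` (moving image/mask and point validity
#'   updated; the fixed side is untouched).
#' @export
degrade_phantom <- function(ph, mode = c("tear", "fold", "partial"),
                            severity) {
  mode <- match.arg(mode)
  stopifnot(severity >= 0, severity <= 1)
  if (severity == 0) return(ph)
  size <- ph$size
  px <- as_pixels(ph$moving)
  mask <- ph$moving_mask
  gt <- ph$gt_moving
  yy <- rep(seq_len(size) - 0.5, times = size)
  xx <- rep(seq_len(size) - 0.5, each = size)
  bg <- 0.93
  with_seed(derive_seed(ph$seed, 202L), {
    if (mode == "partial") {
      psi <- stats::runif(1, 0, 2 * pi)
      proj <- yy * cos(psi) + xx * sin(psi)
      pm <- matrix(proj, size, size)
      cutoff <- stats::quantile(pm[mask > 0], 1 - severity)
      destroyed <- pm > cutoff
      gt_proj <- gt$coords[, 1] * cos(psi) + gt$coords[, 2] * sin(psi)
      gone <- gt$valid & gt_proj > cutoff
    } else if (mode == "tear") {
      cv <- ph$geometry$organ
      psi <- stats::runif(1, 0, 2 * pi)
      tip <- curve_point(cv, psi, shrink = 1 - 0.8 * severity)
      outer_pt <- curve_point(cv, psi, shrink = 1.3)
      # crack: points close to the segment tip -> outer_pt
      seg <- outer_pt - tip
      len2 <- sum(seg^2)
      tproj <- clamp(((yy - tip[1]) * seg[1] + (xx - tip[2]) * seg[2]) / len2,
                     0, 1)
      dy <- yy - (tip[1] + tproj * seg[1])
      dx <- xx - (tip[2] + tproj * seg[2])
      width <- 2 + 10 * severity
      destroyed <- matrix(sqrt(dy^2 + dx^2) < width * (0.3 + 0.7 * tproj),
                          size, size)
      gtp <- gt$coords
      gproj <- clamp(((gtp[, 1] - tip[1]) * seg[1] +
                        (gtp[, 2] - tip[2]) * seg[2]) / len2, 0, 1)
      gd <- sqrt((gtp[, 1] - (tip[1] + gproj * seg[1]))^2 +
                   (gtp[, 2] - (tip[2] + gproj * seg[2]))^2)
      gone <- gt$valid & gd < width * (0.3 + 0.7 * gproj)
    } else { # fold
      psi <- stats::runif(1, 0, 2 * pi)
      proj <- yy * cos(psi) + xx * sin(psi)
      pm <- matrix(proj, size, size)
      hi <- stats::quantile(pm[mask > 0], 1)
      w <- severity * 0.2 * size
      strip <- pm > (hi - w)
      # mirror across the strip's inner boundary
      refl <- 2 * (hi - w) - proj
      ry <- yy + (refl - proj) * cos(psi)
      rx <- xx + (refl - proj) * sin(psi)
      mirrored <- bilinear_sample(px, ry, rx, fill = bg)
      px[strip] <- 0.85 * matrix(mirrored, size, size)[strip]
      destroyed <- strip
      gproj <- gt$coords[, 1] * cos(psi) + gt$coords[, 2] * sin(psi)
      gone <- gt$valid & gproj > (hi - w)
    }
    if (mode != "fold") {
      px[destroyed] <- bg
    }
    mask[destroyed] <- 0
    valid <- gt$valid & !gone
    out <- ph
    out$moving <- hp_image(clamp(px, 0, 1), "histology")
    out$moving_mask <- mask
    out$gt_moving <- hp_points(gt$coords * valid, valid = valid)
    out$gt_fixed <- hp_points(ph$gt_fixed$coords * valid, valid = valid)
    out$degraded <- list(mode = mode, severity = severity)
    out
  })
}
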