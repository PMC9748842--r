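# Image container, intensity normalization, foreground detection, and the
# center-zoom used to standardize inputs before landmark selection and the
# network.
#
# Coordinate convention (fixed package-wide): points are (y, x) = (row, col),
# 0-based and continuous; pixel i spans [i, i + 1), so its center sits at
# i + 0.5.  Matrices are stored in the natural R orientation (row = y).

#' 2-D image with modality tag
#'
#' Lightweight container for a single-channel image in `[0, 1]`. `modality`
#' selects which network branch (and which foreground polarity) applies:
#' histology slides are dark tissue on a light field, MR is the reverse.
#'
#' @param pixels numeric matrix of intensities.
#' @param modality `"histology"` or `"mr"`.
#' @return an object of class `hp_image`.
#' @export
hp_image <- function(pixels, modality = c("histology", "mr")) {
  modality <- match.arg(modality)
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  structure(list(pixels = pixels, modality = modality), class = "hp_image")
}

#' @export
print.hp_image <- function(x, ...) {
  cat(sprintf("<hp_image %dx%d, modality=%s, range=[%.3f, %.3f]>\n",
              nrow(x$pixels), ncol(x$pixels), x$modality,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

# Accept either an hp_image or a bare matrix.
as_pixels <- function(img) {
  if (inherits(img, "hp_image")) img$pixels else img
}

img_modality <- function(img, default = "histology") {
  if (inherits(img, "hp_image")) img$modality else default
}

#' Normalize a raw raster to a single-channel `[0, 1]` image
#'
#' RGB inputs are first reduced to grayscale with Rec. 709 luma weights,
#' then intensities are min-max rescaled to `[0, 1]`. A constant image maps
#' to all zeros. The operation is idempotent.
#'
#' @param raw 2-D matrix or 3-D array (H x W x channels).
#' @param modality `"histology"` or `"mr"`.
#' @return an `hp_image`.
#' @export
normalize_image <- function(raw, modality = c("histology", "mr")) {
  modality <- match.arg(modality)
  if (inherits(raw, "hp_image")) raw <- raw$pixels
  d <- dim(raw)
  if (is.null(d) || !(length(d) %in% c(2L, 3L))) {
    stop("normalize_image: `raw` must be a 2-D matrix or 3-D array")
  }
  if (length(d) == 3L) {
    if (d[3] == 1L) {
      raw <- raw[, , 1L]
    } else if (d[3] >= 3L) {
      # luma conversion; alpha channels (if any) are ignored
      raw <- 0.2126 * raw[, , 1L] + 0.7152 * raw[, , 2L] + 0.0722 * raw[, , 3L]
    } else {
      stop("normalize_image: 3-D input must have 1 or >= 3 channels")
    }
  }
  raw <- matrix(as.numeric(raw), nrow(raw), ncol(raw))
  rng <- range(raw)
  px <- if (rng[2] > rng[1]) (raw - rng[1]) / (rng[2] - rng[1]) else raw * 0
  hp_image(px, modality)
}

# Otsu threshold on a 256-bin histogram (maximizes between-class variance).
otsu_threshold <- function(px) {
  rng <- range(px)
  if (rng[2] <= rng[1]) return(rng[1])
  nb <- 256L
  h <- as.numeric(
    tabulate(pmin(nb, 1L + floor((px - rng[1]) / (rng[2] - rng[1]) * nb)), nb))
  w <- cumsum(h)
  mu <- cumsum(h * seq_len(nb))
  total <- w[nb]
  mu_t <- mu[nb]
  w0 <- w[-nb]
  w1 <- total - w0
  num <- (mu_t * w0 - mu[-nb] * total)^2
  den <- w0 * w1
  bcv <- ifelse(den > 0, num / den, 0)
  k <- which.max(bcv)
  rng[1] + (k / nb) * (rng[2] - rng[1])
}

#' Bounding box of the imaged organ
#'
#' Finds the foreground with Otsu thresholding (dark-on-light for histology,
#' light-on-dark for MR), drops connected components smaller than
#' `min_component_frac` of the image area, and returns the tight box around
#' what remains.
#'
#' @param img `hp_image` (or matrix; polarity then defaults to histology).
#' @param min_component_frac components smaller than this fraction of the
#'   image area are treated as specks and removed (default 0.1%).
#' @return integer vector `c(y0, x0, y1, x1)`, 0-based inclusive pixel bounds.
#' @export
foreground_bbox <- function(img, min_component_frac = 0.001) {
  px <- as_pixels(img)
  modality <- img_modality(img)
  if (diff(range(px)) == 0) {
    stop("foreground_bbox: empty foreground (constant image)")
  }
  th <- otsu_threshold(px)
  fg <- if (modality == "histology") px < th else px > th
  if (!any(fg)) stop("foreground_bbox: empty foreground")
  lab <- EBImage::imageData(EBImage::bwlabel(fg * 1))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_component_frac * length(px))
  fg <- matrix(lab %in% keep, nrow(px), ncol(px))
  if (!any(fg)) stop("foreground_bbox: empty foreground after speck removal")
  idx <- which(fg, arr.ind = TRUE)
  c(min(idx[, 1]) - 1L, min(idx[, 2]) - 1L,
    max(idx[, 1]) - 1L, max(idx[, 2]) - 1L)
}

#' Affine zoom transform (uniform scale + per-axis offset)
#'
#' Maps original-frame coordinates to zoomed-frame coordinates as
#' `q' = scale * q + offset`.
#'
#' @param scale positive real.
#' @param offset numeric length-2 `(y, x)` offset in pixels.
#' @return object of class `hp_zoom`.
#' @export
hp_zoom <- function(scale, offset = c(0, 0)) {
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0,
            length(offset) == 2L)
  structure(list(scale = scale, offset = as.numeric(offset)), class = "hp_zoom")
}

#' Apply a zoom transform to coordinates
#' @param zt `hp_zoom`.
#' @param coords m x 2 matrix of (y, x) points.
#' @return m x 2 matrix of mapped points.
#' @export
zoom_apply <- function(zt, coords) {
  coords <- rbind(coords)
  sweep(coords * zt$scale, 2, zt$offset, "+")
}

#' Invert a zoom transform
#' @param zt `hp_zoom`.
#' @return the inverse `hp_zoom`.
#' @export
zoom_invert <- function(zt) {
  hp_zoom(1 / zt$scale, -zt$offset / zt$scale)
}

# Bilinear sampling of `px` at continuous (y, x) coordinates.  Values are
# attached to pixel centers (i + 0.5); samples whose 2x2 support leaves the
# image blend with `fill`.
bilinear_sample <- function(px, y, x, fill = 0) {
  .bilinear_sample(px, as.numeric(y), as.numeric(x), fill)
}

# Backward-warp an image: out[q] = px[map_fn(q)] with bilinear sampling.
# map_fn takes an m x 2 matrix of output-frame coords and returns the
# source-frame coords.
warp_backward <- function(px, map_fn, out_h, out_w, fill = 0) {
  yy <- rep(seq_len(out_h) - 0.5, times = out_w)
  xx <- rep(seq_len(out_w) - 0.5, each = out_h)
  src <- map_fn(cbind(yy, xx))
  matrix(bilinear_sample(px, src[, 1], src[, 2], fill = fill), out_h, out_w)
}

#' Center and zoom an image so its foreground box fills the frame
#'
#' The box content is scaled so its longer side spans `out_size - 2 * pad`
#' pixels (aspect preserved) and translated so the box center lands at the
#' frame center. Out-of-frame samples are filled with the median intensity of
#' the original image border, so no artificial dark frame is introduced.
#'
#' @param img `hp_image`.
#' @param bbox `c(y0, x0, y1, x1)` 0-based inclusive bounds (see
#'   [foreground_bbox()]).
#' @param pad margin in output pixels on either side of the longer axis
#'   (default 50).
#' @param out_size output frame side (default 512).
#' @return list with `image` (`hp_image`) and `zoom` (`hp_zoom` mapping
#'   original coordinates to output coordinates).
#' @export
center_zoom <- function(img, bbox, pad = 50, out_size = 512) {
  px <- as_pixels(img)
  stopifnot(length(bbox) == 4L, pad >= 0, out_size > 2 * pad)
  y0 <- bbox[1]; x0 <- bbox[2]; y1 <- bbox[3]; x1 <- bbox[4]
  if (y0 < 0 || x0 < 0 || y1 > nrow(px) - 1 || x1 > ncol(px) - 1 || y1 < y0 || x1 < x0) {
    stop("center_zoom: bbox exceeds the image or is empty")
  }
  ext <- max(y1 - y0 + 1, x1 - x0 + 1)
  scale <- (out_size - 2 * pad) / ext
  c_in <- c((y0 + y1 + 1) / 2, (x0 + x1 + 1) / 2)
  offset <- c(out_size / 2, out_size / 2) - scale * c_in
  zt <- hp_zoom(scale, offset)
  inv <- zoom_invert(zt)
  border <- c(px[1, ], px[nrow(px), ], px[, 1], px[, ncol(px)])
  fill <- stats::median(border)
  out <- warp_backward(px, function(q) zoom_apply(inv, q), out_size, out_size,
                       fill = fill)
  list(image = hp_image(clamp(out, 0, 1), img_modality(img)), zoom = zt)
}

#' Read a PNG or TIFF raster
#' @param path file path; format chosen by extension.
#' @return numeric matrix or 3-D array with intensities in `[0, 1]`.
#' @export
read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else {
    stop("read_raster: unsupported extension '", ext, "' (use png/tif/tiff)")
  }
}

#' Write a grayscale image as PNG or TIFF
#' @param img `hp_image` or matrix in `[0, 1]`.
#' @param path output path; format chosen by extension.
#' @export
write_raster <- function(img, path) {
  px <- clamp(as_pixels(img), 0, 1)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(px, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(px, path)
  } else {
    stop("write_raster: unsupported extension '", ext, "'")
  }
  invisible(path)
}
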