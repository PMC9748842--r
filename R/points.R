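# Point sets: ordered (y, x) coordinates with an explicit validity mask and
# an optional edge/interior class.  The network's (0, 0) padding sentinel is
# honored at model I/O boundaries; internally validity is always the mask.

#' Point set with validity mask and optional class labels
#'
#' @param coords m x 2 numeric matrix of (y, x) coordinates in pixels.
#' @param valid logical vector of length m (default all `TRUE`). Invalid
#'   rows carry the `(0, 0)` sentinel.
#' @param class optional character vector (`"edge"`/`"interior"`) or `NA`.
#' @return object of class `hp_points`.
#' @export
hp_points <- function(coords, valid = NULL, class = NULL) {
  if (is.null(coords)) coords <- matrix(numeric(0), 0, 2)
  coords <- rbind(coords)
  if (ncol(coords) != 2L) stop("hp_points: coords must be m x 2")
  m <- nrow(coords)
  valid <- valid %||% rep(TRUE, m)
  stopifnot(is.logical(valid), length(valid) == m)
  if (!is.null(class)) {
    stopifnot(length(class) == m)
    class <- as.character(class)
  }
  coords[!valid, ] <- 0
  structure(list(coords = unname(coords), valid = valid, class = class),
            class = "hp_points")
}

#' @export
print.hp_points <- function(x, ...) {
  cat(sprintf("<hp_points: %d points (%d valid%s)>\n",
              nrow(x$coords), sum(x$valid),
              if (!is.null(x$class)) sprintf(", %d edge", sum(x$class == "edge", na.rm = TRUE)) else ""))
  invisible(x)
}

n_valid <- function(pts) sum(pts$valid)

valid_coords <- function(pts) pts$coords[pts$valid, , drop = FALSE]

as_points <- function(x) {
  if (inherits(x, "hp_points")) x else hp_points(x)
}

#' Pad a point set to fixed length with (0, 0) sentinels
#'
#' The network consumes fixed-length point lists; shorter sets are padded
#' with invalid `(0, 0)` rows. Invalid rows already present are dropped and
#' re-appended at the end so valid points always come first.
#'
#' @param points `hp_points`.
#' @param L target length (default 75).
#' @return `hp_points` of length exactly `L`.
#' @export
pad_points <- function(points, L = 75L) {
  points <- as_points(points)
  nv <- n_valid(points)
  if (nv > L) {
    stop(sprintf(paste0("pad_points: %d valid points exceed L = %d; raise L ",
                        "or thin the point set"), nv, L))
  }
  keep <- points$valid
  coords <- rbind(points$coords[keep, , drop = FALSE],
                  matrix(0, L - nv, 2))
  cls <- NULL
  if (!is.null(points$class)) {
    cls <- c(points$class[keep], rep(NA_character_, L - nv))
  }
  hp_points(coords, valid = c(rep(TRUE, nv), rep(FALSE, L - nv)), class = cls)
}

#' Map a point set through a zoom transform
#'
#' Valid points are mapped affinely; invalid sentinel rows pass through
#' unchanged (and stay invalid).
#'
#' @param points `hp_points`.
#' @param zt `hp_zoom`.
#' @return transformed `hp_points`.
#' @export
apply_zoom_to_points <- function(points, zt) {
  points <- as_points(points)
  coords <- points$coords
  if (any(points$valid)) {
    coords[points$valid, ] <- zoom_apply(zt, coords[points$valid, , drop = FALSE])
  }
  hp_points(coords, valid = points$valid, class = points$class)
}

#' Read a point CSV ("id,y,x[,class]")
#'
#' Coordinates are 0-based pixels in the (y, x) = (row, col) convention.
#'
#' @param path CSV path.
#' @return `hp_points`.
#' @export
read_points <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "y", "x")
  if (!all(need %in% names(df))) {
    stop("read_points: CSV must have header id,y,x[,class]")
  }
  cls <- if ("class" %in% names(df)) as.character(df$class) else NULL
  hp_points(cbind(df$y, df$x), class = cls)
}

#' Write a point CSV ("id,y,x[,class]")
#'
#' Only valid points are written; ids are 0-based row indices.
#'
#' @param points `hp_points`.
#' @param path output CSV path.
#' @export
write_points <- function(points, path) {
  points <- as_points(points)
  keep <- which(points$valid)
  df <- data.frame(id = seq_along(keep) - 1L,
                   y = points$coords[keep, 1],
                   x = points$coords[keep, 2])
  if (!is.null(points$class)) df$class <- points$class[keep]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
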