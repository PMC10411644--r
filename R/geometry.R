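#' Screen/image geometry for pixel to degrees-visual-angle conversion
#'
#' The stimulus image is assumed to span a fixed extent in degrees visual
#' angle (dva). The default extents (29.7 x 22.3 dva) correspond to a
#' full-screen scene viewed at roughly 64 cm. The pixel-to-dva map is linear
#' and axis-wise (isotropy is not assumed): the full image width in pixels
#' maps to `width_dva`, the full height to `height_dva`. The origin is the
#' image top-left corner, x grows rightward, y downward, pixel indices are
#' 0-based.
#'
#' @param width_px,height_px Image dimensions in pixels.
#' @param width_dva,height_dva Image extents in degrees visual angle.
#' @return An object of class `screen_geometry`.
#' @examples
#' geom <- screen_geometry(800, 600)
#' px_to_dva(c(800, 0), geom) # image right edge -> 29.7 dva
#' @export
screen_geometry <- function(width_px, height_px,
                            width_dva = 29.7, height_dva = 22.3) {
  vals <- c(width_px, height_px, width_dva, height_dva)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("screen_geometry dimensions must be finite and positive")
  }
  structure(
    list(width_px = width_px, height_px = height_px,
         width_dva = width_dva, height_dva = height_dva,
         px_per_dva_x = width_px / width_dva,
         px_per_dva_y = height_px / height_dva),
    class = "screen_geometry"
  )
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("<screen_geometry> %d x %d px = %.1f x %.1f dva\n",
              x$width_px, x$height_px, x$width_dva, x$height_dva))
  invisible(x)
}

#' Convert pixel coordinates to degrees visual angle
#'
#' @param point A length-2 numeric `c(x, y)` in pixels, or a two-column
#'   matrix / data frame of points.
#' @param geom A [screen_geometry()].
#' @return Coordinates in dva, same shape as the input.
#' @export
px_to_dva <- function(point, geom) {
  stopifnot(inherits(geom, "screen_geometry"))
  xy <- as_xy(point)
  if (any(!is.finite(xy))) abort("px_to_dva: non-finite input coordinates")
  out <- cbind(x = xy[, 1] / geom$px_per_dva_x,
               y = xy[, 2] / geom$px_per_dva_y)
  restore_xy(out, point)
}

#' Convert dva coordinates to pixels
#'
#' Inverse of [px_to_dva()].
#' @inheritParams px_to_dva
#' @export
dva_to_px <- function(point, geom) {
  stopifnot(inherits(geom, "screen_geometry"))
  xy <- as_xy(point)
  if (any(!is.finite(xy))) abort("dva_to_px: non-finite input coordinates")
  out <- cbind(x = xy[, 1] * geom$px_per_dva_x,
               y = xy[, 2] * geom$px_per_dva_y)
  restore_xy(out, point)
}

as_xy <- function(point) {
  if (is.matrix(point) || is.data.frame(point)) {
    m <- as.matrix(point)
    if (ncol(m) != 2) abort("expected two coordinate columns")
    storage.mode(m) <- "double"
    m
  } else {
    if (length(point) != 2) abort("expected a length-2 c(x, y) point")
    matrix(as.double(point), ncol = 2)
  }
}

restore_xy <- function(out, point) {
  if (is.matrix(point) || is.data.frame(point)) out else drop(out)
}
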