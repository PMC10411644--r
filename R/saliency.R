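#' Saliency maps and local salience sums
#'
#' A saliency map is a nonnegative per-pixel grid (arbitrary salience
#' units) over the image, either computed by the simplified graph-based
#' algorithm in [compute_gbvs()] or supplied precomputed (e.g. maps from
#' the original GBVS release, read with [read_saliency()]).
#'
#' @param image_id Image identifier.
#' @param values Numeric matrix (`height_px` x `width_px`), all values >= 0.
#' @param geom A [screen_geometry()].
#' @return An object of class `saliency_map`.
#' @export
saliency_map <- function(image_id, values, geom) {
  stopifnot(inherits(geom, "screen_geometry"))
  if (nrow(values) != geom$height_px || ncol(values) != geom$width_px) {
    abort("saliency values do not match the image geometry")
  }
  if (any(values < 0)) abort("saliency values must be nonnegative")
  structure(list(image_id = image_id, values = values, geom = geom),
            class = "saliency_map")
}

#' Graph-based visual saliency (simplified)
#'
#' A lightweight re-implementation of graph-based visual saliency: a
#' luminance feature map is computed at three spatial scales; at each scale
#' a fully connected lattice graph is built whose edge weights combine
#' feature dissimilarity `|f_i - f_j|` with a Gaussian distance decay, the
#' row-normalized weights define a Markov chain, and the chain's
#' equilibrium distribution is the scale's activation. Activations are
#' upsampled, averaged and normalized to sum 1. This captures the
#' center-surround "mass concentrates on dissimilar nodes" behaviour of the
#' original algorithm but not its exact channel set; where fidelity to
#' published saliency values matters, supply precomputed maps instead.
#'
#' A constant image has no feature contrast and yields the uniform map.
#'
#' @param image Numeric matrix (grayscale, any nonnegative scale) or a
#'   3-dimensional array whose third dimension is RGB.
#' @param geom A [screen_geometry()] matching the image.
#' @param scale_widths Node-grid widths (coarsest lattice resolutions).
#' @param sigma_frac Distance-decay length as a fraction of grid width.
#' @param n_iter,tol Power-iteration controls for the equilibrium.
#' @return A [saliency_map()] whose values sum to 1.
#' @export
compute_gbvs <- function(image, geom, scale_widths = c(32, 16, 8),
                         sigma_frac = 0.15, n_iter = 200, tol = 1e-10) {
  if (length(dim(image)) == 3) {
    image <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  }
  H <- nrow(image); W <- ncol(image)
  acc <- matrix(0, H, W)
  for (w in scale_widths) {
    h <- max(2, round(w * H / W))
    w <- max(2, w)
    f <- block_mean(image, h, w)
    a <- lattice_equilibrium(f, sigma_frac, n_iter, tol)
    acc <- acc + upsample_nearest(a, H, W) / length(scale_widths)
  }
  if (sum(acc) <= 0) acc[] <- 1
  saliency_map(image_id = NA_character_, values = acc / sum(acc), geom = geom)
}

block_mean <- function(img, h, w) {
  H <- nrow(img); W <- ncol(img)
  ri <- pmin(h, floor((seq_len(H) - 1) / H * h) + 1)
  ci <- pmin(w, floor((seq_len(W) - 1) / W * w) + 1)
  cell <- ri[row(img)] + (ci[col(img)] - 1) * h
  sums <- tapply(as.numeric(img), cell, mean)
  out <- matrix(0, h, w)
  out[as.integer(names(sums))] <- sums
  out
}

lattice_equilibrium <- function(f, sigma_frac, n_iter, tol) {
  h <- nrow(f); w <- ncol(f)
  n <- h * w
  rr <- rep(seq_len(h), times = w)
  cc <- rep(seq_len(w), each = h)
  d2 <- outer(rr, rr, `-`)^2 + outer(cc, cc, `-`)^2
  sigma <- max(sigma_frac * w, 1)
  decay <- exp(-d2 / (2 * sigma^2))
  dis <- abs(outer(as.numeric(f), as.numeric(f), `-`))
  Wt <- dis * decay
  rs <- rowSums(Wt)
  if (all(rs < 1e-12)) return(matrix(1 / n, h, w)) # no contrast: uniform
  P <- Wt / pmax(rs, 1e-12)
  v <- rep(1 / n, n)
  for (i in seq_len(n_iter)) {
    v2 <- as.numeric(crossprod(P, v))
    v2 <- v2 / sum(v2)
    if (max(abs(v2 - v)) < tol) { v <- v2; break }
    v <- v2
  }
  matrix(v, h, w)
}

upsample_nearest <- function(a, H, W) {
  h <- nrow(a); w <- ncol(a)
  ri <- pmin(h, floor((seq_len(H) - 1) / H * h) + 1)
  ci <- pmin(w, floor((seq_len(W) - 1) / W * w) + 1)
  a[ri, ci, drop = FALSE]
}

#' Sum of saliency values within a foveation disc
#'
#' Sums map values over pixels whose centers lie within the disc of
#' `radius` dva around `point` (same disc geometry as [labels_at()]).
#' Monotone non-decreasing in `radius`; an off-image point yields `NA`.
#'
#' @param point dva pair `c(x, y)`.
#' @param smap A [saliency_map()].
#' @param radius Disc radius, dva.
#' @return Scalar salience sum (arbitrary units).
#' @export
salience_at <- function(point, smap, radius = 0.5) {
  stopifnot(inherits(smap, "saliency_map"))
  g <- smap$geom
  if (point[1] < 0 || point[1] > g$width_dva ||
      point[2] < 0 || point[2] > g$height_dva) {
    warn("salience_at: point off image, returning NA")
    return(NA_real_)
  }
  idx <- disc_pixel_index(point[1], point[2], g, radius)
  sum(smap$values[idx])
}

# batched disc sums for the series builder
salience_at_points <- function(x_dva, y_dva, smap, radius = 0.5) {
  vapply(seq_along(x_dva), function(i) {
    suppressWarnings(salience_at(c(x_dva[i], y_dva[i]), smap, radius))
  }, numeric(1))
}

#' @rdname saliency_map
#' @param path Whitespace-delimited matrix text file.
#' @export
read_saliency <- function(path, image_id, geom) {
  mat <- as.matrix(utils::read.table(path))
  dimnames(mat) <- NULL
  saliency_map(image_id, mat, geom)
}

#' @rdname saliency_map
#' @param smap A [saliency_map()] to write.
#' @export
write_saliency <- function(smap, path) {
  utils::write.table(smap$values, path, row.names = FALSE, col.names = FALSE)
  invisible(smap)
}
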