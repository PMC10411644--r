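#' Scene annotation: labeled binary object masks over an image
#'
#' A scene annotation holds, for one image, a set of binary pixel masks
#' with semantic labels (e.g. `inner_face`, `head`, `body`, `animal`,
#' `inanimate_object`, `text`) plus the image geometry, mirroring
#' OSIE/OSIEplus-style object annotations. Masks are logical matrices with
#' `height_px` rows and `width_px` columns; pixel `[r, c]` covers the
#' 0-based pixel `(ix, iy) = (c - 1, r - 1)` whose center sits at
#' `(ix + 0.5, iy + 0.5)` px. Area fractions are percentages of image area.
#'
#' When the masks are pairwise disjoint a composite integer label matrix is
#' precomputed, which makes point queries (and the event-series builder)
#' fast; overlapping masks are fully supported through the per-object path.
#'
#' @param image_id Image identifier.
#' @param geom A [screen_geometry()] matching the mask dimensions.
#' @param masks List of logical matrices (one per object), or `NULL` when
#'   `label_mat` is given (disjoint objects encoded in one integer matrix,
#'   0 = background) — the memory-lean form used for large scene sets.
#' @param labels List of character vectors (labels per object), or a
#'   character vector of semicolon-joined labels.
#' @param object_ids Optional integer ids; defaults to `seq_along(labels)`.
#' @param label_mat Optional integer label matrix in place of `masks`.
#' @return An object of class `scene_annotation` with fields `image_id`,
#'   `geom`, `objects` (tibble: `object_id`, `labels`, `area_fraction`),
#'   `masks` (possibly `NULL`) and `label_mat` (`NULL` if masks overlap).
#' @export
scene_annotation <- function(image_id, geom, masks = NULL, labels,
                             object_ids = NULL, label_mat = NULL) {
  stopifnot(inherits(geom, "screen_geometry"))
  if (is.character(labels)) labels <- strsplit(labels, ";", fixed = TRUE)
  if (is.null(masks) && is.null(label_mat)) {
    abort("provide masks or a label_mat")
  }
  if (any(lengths(labels) == 0)) abort("every object needs at least one label")
  known <- c("inner_face", "head", "eyes", "mouth", "nose", "body", "hands",
             "legs", "person", "animal", "inanimate_object", "text",
             "touched", "background")
  unk <- setdiff(unique(unlist(labels)), known)
  if (length(unk) > 0) {
    warn(paste("unknown annotation labels:", paste(unk, collapse = ", ")))
  }
  if (is.null(object_ids)) object_ids <- seq_along(labels)
  object_ids <- as.integer(object_ids)
  total <- geom$width_px * geom$height_px

  if (!is.null(masks)) {
    if (length(masks) != length(labels)) {
      abort("masks and labels must have the same length")
    }
    for (m in masks) {
      if (!is.logical(m)) abort("masks must be logical matrices")
      if (nrow(m) != geom$height_px || ncol(m) != geom$width_px) {
        abort("mask dimensions do not match the image geometry")
      }
    }
    area <- vapply(masks, function(m) 100 * sum(m) / total, numeric(1))
    cover <- Reduce(`+`, lapply(masks, function(m) m * 1L))
    if (length(masks) > 0 && max(cover) <= 1L) {
      label_mat <- matrix(0L, geom$height_px, geom$width_px)
      for (i in seq_along(masks)) label_mat[masks[[i]]] <- object_ids[i]
    } else {
      label_mat <- NULL
    }
    masks <- stats::setNames(masks, object_ids)
  } else {
    if (nrow(label_mat) != geom$height_px || ncol(label_mat) != geom$width_px) {
      abort("label_mat dimensions do not match the image geometry")
    }
    counts <- tabulate(label_mat, nbins = max(object_ids))
    area <- 100 * counts[object_ids] / total
  }
  structure(
    list(image_id = image_id, geom = geom,
         objects = tibble::tibble(object_id = object_ids,
                                  labels = labels, area_fraction = area),
         masks = masks, label_mat = label_mat),
    class = "scene_annotation"
  )
}

# logical mask of one object, whichever storage form is present
object_mask <- function(annot, id) {
  if (!is.null(annot$masks)) annot$masks[[as.character(id)]]
  else annot$label_mat == id
}

#' @export
print.scene_annotation <- function(x, ...) {
  cat(sprintf("<scene_annotation> image %s: %d objects, %d x %d px\n",
              x$image_id, nrow(x$objects), x$geom$width_px, x$geom$height_px))
  invisible(x)
}

#' Objects and labels overlapping a foveation disc around a point
#'
#' Returns every object whose mask intersects the disc of `radius` dva
#' around `point` (the approximately foveated area; default 0.5 dva). The
#' disc is evaluated in pixel space with axis-wise pixel radii, so
#' anisotropic pixel grids are handled; a pixel belongs to the disc if its
#' center lies inside. `radius = 0` reduces to point-in-mask membership.
#'
#' @param point dva pair `c(x, y)`.
#' @param annot A [scene_annotation()].
#' @param radius Foveation radius, dva.
#' @return List with `object_ids` (integer) and `labels` (character union).
#' @export
labels_at <- function(point, annot, radius = 0.5) {
  stopifnot(inherits(annot, "scene_annotation"))
  g <- annot$geom
  if (point[1] < 0 || point[1] > g$width_dva ||
      point[2] < 0 || point[2] > g$height_dva) {
    warn("labels_at: point off image, returning empty set")
    return(list(object_ids = integer(), labels = character()))
  }
  idx <- disc_pixel_index(point[1], point[2], g, radius)
  if (length(idx) == 0) return(list(object_ids = integer(), labels = character()))
  if (!is.null(annot$label_mat)) {
    ids <- sort(unique(annot$label_mat[idx]))
    ids <- ids[ids > 0]
    hit <- annot$objects$object_id %in% ids
  } else {
    hit <- vapply(annot$masks, function(m) any(m[idx]), logical(1))
    ids <- annot$objects$object_id[hit]
  }
  list(object_ids = ids,
       labels = unique(unlist(annot$objects$labels[hit])))
}

# linear indices (into a height x width matrix) of pixels whose centers lie
# within the (possibly anisotropic) disc of `radius` dva around a dva point
disc_pixel_index <- function(x_dva, y_dva, geom, radius) {
  cx <- x_dva * geom$px_per_dva_x # continuous 0-based px coordinate
  cy <- y_dva * geom$px_per_dva_y
  W <- geom$width_px; H <- geom$height_px
  if (radius == 0) {
    ix <- min(max(floor(cx), 0), W - 1)
    iy <- min(max(floor(cy), 0), H - 1)
    return((ix) * H + iy + 1)
  }
  rx <- radius * geom$px_per_dva_x
  ry <- radius * geom$px_per_dva_y
  xs <- max(0, floor(cx - rx - 0.5)):min(W - 1, ceiling(cx + rx))
  ys <- max(0, floor(cy - ry - 0.5)):min(H - 1, ceiling(cy + ry))
  gx <- rep(xs, each = length(ys))
  gy <- rep(ys, times = length(xs))
  inside <- ((gx + 0.5 - cx) / rx)^2 + ((gy + 0.5 - cy) / ry)^2 <= 1
  gx <- gx[inside]; gy <- gy[inside]
  gx * H + gy + 1
}

# batched point query against the composite label matrix (disjoint masks);
# returns an n x k integer matrix of object ids (0 = background / outside)
query_object_ids <- function(x_dva, y_dva, annot, radius = 0.5) {
  g <- annot$geom
  if (is.null(annot$label_mat)) {
    # overlapping masks: per-point fallback
    n <- length(x_dva)
    kmax <- max(1, nrow(annot$objects))
    out <- matrix(0L, n, kmax)
    for (i in seq_len(n)) {
      la <- suppressWarnings(labels_at(c(x_dva[i], y_dva[i]), annot, radius))
      if (length(la$object_ids) > 0) {
        out[i, seq_along(la$object_ids)] <- la$object_ids
      }
    }
    return(out)
  }
  cx <- x_dva * g$px_per_dva_x
  cy <- y_dva * g$px_per_dva_y
  rx <- max(radius * g$px_per_dva_x, 1e-9)
  ry <- max(radius * g$px_per_dva_y, 1e-9)
  m <- ceiling(max(rx, ry)) + 1L
  off <- expand.grid(ox = -m:m, oy = -m:m)
  # drop offsets that cannot fall inside the disc for any fractional
  # point position (the pixel center is within 1 px of the offset)
  feas <- (pmax(abs(off$ox) - 1.5, 0) / rx)^2 +
    (pmax(abs(off$oy) - 1.5, 0) / ry)^2 <= 1
  off <- off[feas, , drop = FALSE]
  W <- g$width_px; H <- g$height_px
  n <- length(cx)
  bx <- floor(cx); by <- floor(cy)
  lm <- annot$label_mat
  ids <- matrix(0L, n, nrow(off))
  for (j in seq_len(nrow(off))) {
    gx <- bx + off$ox[j]
    gy <- by + off$oy[j]
    ok <- gx >= 0 & gx < W & gy >= 0 & gy < H &
      ((gx + 0.5 - cx) / rx)^2 + ((gy + 0.5 - cy) / ry)^2 <= 1
    lin <- gx[ok] * H + gy[ok] + 1
    col <- integer(n)
    col[ok] <- lm[lin]
    ids[, j] <- col
  }
  ids
}

#' Load a scene annotation from text files
#'
#' Canonical text format: an integer-labeled mask matrix (whitespace
#' delimited, `height_px` rows, 0 = background) plus a TSV label table with
#' columns `object_id` and `labels` (semicolon-joined).
#'
#' @param mask_file Path to the label-matrix text file.
#' @param labels_file Path to the label table TSV.
#' @param image_id Image identifier.
#' @param geom A [screen_geometry()]; dimensions must match the matrix.
#' @return A [scene_annotation()].
#' @export
load_annotation <- function(mask_file, labels_file, image_id, geom) {
  mat <- as.matrix(utils::read.table(mask_file))
  dimnames(mat) <- NULL
  if (nrow(mat) != geom$height_px || ncol(mat) != geom$width_px) {
    abort(sprintf("mask matrix is %d x %d but geometry says %d x %d",
                  nrow(mat), ncol(mat), geom$height_px, geom$width_px))
  }
  tab <- readr::read_tsv(labels_file, show_col_types = FALSE, progress = FALSE)
  ids <- as.integer(tab$object_id)
  storage.mode(mat) <- "integer"
  scene_annotation(image_id, geom, labels = tab$labels, object_ids = ids,
                   label_mat = mat)
}

#' Write a scene annotation to the canonical text format
#'
#' Requires disjoint masks (an integer label matrix must exist).
#' @param annot A [scene_annotation()].
#' @param mask_file,labels_file Output paths.
#' @export
write_annotation <- function(annot, mask_file, labels_file) {
  if (is.null(annot$label_mat)) {
    abort("write_annotation requires disjoint masks")
  }
  utils::write.table(annot$label_mat, mask_file, row.names = FALSE,
                     col.names = FALSE)
  tab <- tibble::tibble(
    object_id = annot$objects$object_id,
    labels = vapply(annot$objects$labels, paste, character(1),
                    collapse = ";"))
  readr::write_tsv(tab, labels_file, progress = FALSE)
  invisible(annot)
}
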