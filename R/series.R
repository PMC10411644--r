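#' Build incoming-saccade / intermediate-fixation / target-saccade /
#' target-fixation event series
#'
#' Scans each trial's retained events (empty `flags`) in time order for
#' consecutive quadruples saccade - fixation - saccade - fixation and keeps
#' those satisfying the semantic constraints of the analysis:
#' \itemize{
#'   \item the intermediate fixation lies on an inanimate object;
#'   \item the target saccade's start and landing points touch no common
#'     visual object (evaluated on foveation-disc object sets);
#'   \item the target fixation lies on an inner-face region (category
#'     `face`), a body-without-face region (`body`) or an inanimate object
#'     (`inanimate`); animal-directed series are dropped when
#'     `exclude_animals` is `TRUE`.
#' }
#' Multi-label overlap at a point is resolved by the priority
#' face > animal > body > other person region > inanimate. Consecutiveness
#' is defined on retained events: an excluded event breaks the chain
#' rather than being bridged. A trial's first saccade can therefore never
#' be a target saccade and its last fixation never an intermediate one,
#' but the first saccade may serve as an incoming saccade.
#'
#' @param events Flagged event tibble (after [apply_cascade()]) with an
#'   `image_id` column.
#' @param annotations Named list of [scene_annotation()] keyed by image id
#'   (or a single annotation used for all trials).
#' @param radius Foveation radius in dva for mask overlap.
#' @param exclude_animals Drop series whose target is animal-labeled.
#' @return One row per series: ids (`subject_id`, `trial_id`, `image_id`,
#'   `visual_object_id`), `target_category`, kinematic predictors
#'   (`target_amplitude`, `incoming_amplitude`, `target_size`,
#'   `onset_time`, `angle`), responses (`peak_velocity`,
#'   `intermediate_duration`) and the fixation centers used downstream for
#'   salience sums.
#' @export
build_series <- function(events, annotations, radius = 0.5,
                         exclude_animals = TRUE) {
  if (!"image_id" %in% names(events)) {
    abort("events must carry an image_id column to be matched to annotations")
  }
  if (inherits(annotations, "scene_annotation")) {
    annotations <- stats::setNames(list(annotations),
                                   annotations$image_id)
  }
  ev <- events[is_retained(events), , drop = FALSE]
  ev <- ev[order(ev$subject_id, ev$trial_id, ev$onset), , drop = FALSE]
  n <- nrow(ev)
  if (n < 4) return(empty_series())
  # consecutive retained quadruples via index shifts within trial
  key <- paste(ev$subject_id, ev$trial_id, sep = "\r")
  i1 <- seq_len(n - 3); i2 <- i1 + 1L; i3 <- i1 + 2L; i4 <- i1 + 3L
  hit <- ev$kind[i1] == "saccade" & ev$kind[i2] == "fixation" &
    ev$kind[i3] == "saccade" & ev$kind[i4] == "fixation" &
    key[i1] == key[i4] &
    !is.na(ev$amplitude[i1]) & ev$amplitude[i1] > 0 &
    !is.na(ev$amplitude[i3]) & ev$amplitude[i3] > 0
  i1 <- i1[hit]; i2 <- i2[hit]; i3 <- i3[hit]; i4 <- i4[hit]
  if (length(i1) == 0) return(empty_series())
  cand <- tibble::tibble(
    subject_id = ev$subject_id[i1], trial_id = ev$trial_id[i1],
    image_id = ev$image_id[i1],
    in_dx = ev$x_end[i1] - ev$x_start[i1],
    in_dy = ev$y_end[i1] - ev$y_start[i1],
    incoming_amplitude = ev$amplitude[i1],
    im_x = ev$x_mean[i2], im_y = ev$y_mean[i2],
    intermediate_duration = ev$duration[i2],
    ts_x0 = ev$x_start[i3], ts_y0 = ev$y_start[i3],
    ts_x1 = ev$x_end[i3], ts_y1 = ev$y_end[i3],
    target_amplitude = ev$amplitude[i3],
    peak_velocity = ev$peak_velocity[i3],
    onset_time = ev$onset[i3],
    tf_x = ev$x_mean[i4], tf_y = ev$y_mean[i4])

  parts <- split(cand, cand$image_id)
  out <- lapply(names(parts), function(img) {
    annot <- annotations[[img]]
    if (is.null(annot)) {
      warn(paste("no annotation for image", img, "- trials skipped"))
      return(NULL)
    }
    classify_series(parts[[img]], annot, radius, exclude_animals)
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) return(empty_series())
  dplyr::arrange(res, .data$subject_id, .data$trial_id, .data$onset_time)
}

empty_series <- function() {
  tibble::tibble(
    subject_id = character(), trial_id = character(), image_id = character(),
    visual_object_id = integer(), target_category = character(),
    target_amplitude = double(), incoming_amplitude = double(),
    target_size = double(), onset_time = double(), angle = double(),
    peak_velocity = double(), intermediate_duration = double(),
    intermediate_x = double(), intermediate_y = double(),
    target_x = double(), target_y = double()
  )
}

# category codes, in overlap-priority order (higher wins)
CAT_NONE <- 0L; CAT_INANIMATE <- 1L; CAT_OTHER <- 2L; CAT_BODY <- 3L
CAT_ANIMAL <- 4L; CAT_FACE <- 5L

object_category_codes <- function(annot) {
  vapply(annot$objects$labels, function(lb) {
    if ("inner_face" %in% lb) CAT_FACE
    else if ("animal" %in% lb) CAT_ANIMAL
    else if (any(c("body", "hands", "legs") %in% lb)) CAT_BODY
    else if ("inanimate_object" %in% lb) CAT_INANIMATE
    else CAT_OTHER
  }, integer(1))
}

classify_series <- function(cand, annot, radius, exclude_animals) {
  n <- nrow(cand)
  ids <- annot$objects$object_id
  code_by_id <- integer(max(ids) + 1L) # index id + 1; id 0 = background
  code_by_id[ids + 1L] <- object_category_codes(annot)

  qx <- c(cand$im_x, cand$tf_x, cand$ts_x0, cand$ts_x1)
  qy <- c(cand$im_y, cand$tf_y, cand$ts_y0, cand$ts_y1)
  M <- query_object_ids(qx, qy, annot, radius)
  im_rows <- seq_len(n); tf_rows <- n + im_rows
  s0_rows <- 2L * n + im_rows; s1_rows <- 3L * n + im_rows

  point_code <- row_max_code(M, code_by_id)
  ok_interm <- point_code[im_rows] == CAT_INANIMATE
  tf_code <- point_code[tf_rows]
  ok_target <- tf_code %in% c(CAT_FACE, CAT_BODY, CAT_INANIMATE,
                              if (!exclude_animals) CAT_ANIMAL)
  ok_distinct <- rows_disjoint(M[s0_rows, , drop = FALSE],
                               M[s1_rows, , drop = FALSE])
  keep <- ok_interm & ok_target & ok_distinct
  if (!any(keep)) return(NULL)

  kk <- which(keep)
  Mtf <- M[tf_rows[kk], , drop = FALSE]
  best <- best_object(Mtf, tf_code[kk], ids, code_by_id)
  size_by_id <- stats::setNames(annot$objects$area_fraction, ids)

  cat_name <- c("inanimate", "other", "body", "animal", "face")[tf_code[kk]]
  tibble::tibble(
    subject_id = cand$subject_id[kk], trial_id = cand$trial_id[kk],
    image_id = cand$image_id[kk],
    visual_object_id = best,
    target_category = cat_name,
    target_amplitude = cand$target_amplitude[kk],
    incoming_amplitude = cand$incoming_amplitude[kk],
    target_size = unname(size_by_id[as.character(best)]),
    onset_time = cand$onset_time[kk],
    angle = rel_angle_vec(cand$in_dx[kk], cand$in_dy[kk],
                          cand$ts_x1[kk] - cand$ts_x0[kk],
                          cand$ts_y1[kk] - cand$ts_y0[kk]),
    peak_velocity = cand$peak_velocity[kk],
    intermediate_duration = cand$intermediate_duration[kk],
    intermediate_x = cand$im_x[kk], intermediate_y = cand$im_y[kk],
    target_x = cand$tf_x[kk], target_y = cand$tf_y[kk]
  )
}

row_max_code <- function(M, code_by_id) {
  out <- integer(nrow(M))
  for (j in seq_len(ncol(M))) out <- pmax(out, code_by_id[M[, j] + 1L])
  out
}

# TRUE where the object-id sets of matching rows share no id (> 0)
rows_disjoint <- function(M1, M2) {
  ids <- sort(unique(c(M1[M1 > 0], M2[M2 > 0])))
  if (length(ids) == 0) return(rep(TRUE, nrow(M1)))
  if (max(ids) <= 30) {
    b1 <- integer(nrow(M1)); b2 <- integer(nrow(M2))
    for (j in seq_len(ncol(M1))) {
      b1 <- bitwOr(b1, bitwShiftL(1L, M1[, j]) * (M1[, j] > 0L))
      b2 <- bitwOr(b2, bitwShiftL(1L, M2[, j]) * (M2[, j] > 0L))
    }
    return(bitwAnd(b1, b2) == 0L)
  }
  vapply(seq_len(nrow(M1)), function(i) {
    s1 <- M1[i, ]; s2 <- M2[i, ]
    length(intersect(s1[s1 > 0], s2[s2 > 0])) == 0
  }, logical(1))
}

# per row: object of the resolved category with the largest disc overlap
# (ties broken toward the smaller object id)
best_object <- function(M, code, ids, code_by_id) {
  n <- nrow(M)
  best_id <- rep(NA_integer_, n)
  best_cnt <- integer(n)
  for (id in sort(ids)) {
    cnt <- integer(n)
    for (j in seq_len(ncol(M))) cnt <- cnt + (M[, j] == id)
    better <- cnt > best_cnt & code_by_id[id + 1L] == code
    best_id[better] <- id
    best_cnt[better] <- cnt[better]
  }
  best_id
}

#' Attach low-level salience predictors to an event-series table
#'
#' Completes the predictor record of each series with the salience sums at
#' the intermediate and target fixation centers (disc of `radius` dva).
#' With no saliency maps available the salience fields are set to `NA` and
#' the record retained.
#'
#' @param series Tibble from [build_series()].
#' @param saliency Named list of [saliency_map()] keyed by image id, a
#'   single map, or `NULL`.
#' @param radius Disc radius, dva.
#' @return The series tibble with `gbvs_intermediate` and `gbvs_target`
#'   columns: the model-ready table.
#' @export
featurize <- function(series, saliency = NULL, radius = 0.5) {
  if (inherits(saliency, "saliency_map")) {
    saliency <- stats::setNames(list(saliency), saliency$image_id)
  }
  series$gbvs_intermediate <- NA_real_
  series$gbvs_target <- NA_real_
  if (is.null(saliency)) return(series)
  for (img in unique(series$image_id)) {
    smap <- saliency[[img]]
    if (is.null(smap)) next
    i <- which(series$image_id == img)
    series$gbvs_intermediate[i] <-
      salience_at_points(series$intermediate_x[i], series$intermediate_y[i],
                         smap, radius)
    series$gbvs_target[i] <-
      salience_at_points(series$target_x[i], series$target_y[i], smap, radius)
  }
  series
}

#' Write an event-series table as tidy TSV
#'
#' @param series Series tibble.
#' @param path Output path.
#' @export
write_series <- function(series, path) {
  readr::write_tsv(series, path, progress = FALSE)
  invisible(path)
}
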