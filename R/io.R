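#' Read and write gaze sample streams and event tables
#'
#' Delimited-text I/O with a fixed column schema. Sample streams carry
#' `subject_id`, `trial_id`, (`image_id`,) `t` (ms), `x`, `y` (dva unless a
#' geometry is supplied for pixel input) and `valid`; event tables carry the
#' columns produced by [detect_events()] plus the semicolon-joined `flags`
#' column written by the exclusion cascade.
#'
#' @param path File path (TSV; `.csv` switches to comma).
#' @param geom Optional [screen_geometry()]; if given, `x`/`y` columns are
#'   assumed to be pixels and converted to dva on read.
#' @return A tibble.
#' @name gaze_io
NULL

delim_for <- function(path) if (grepl("\\.csv$", path)) "," else "\t"

#' @rdname gaze_io
#' @export
read_gaze_samples <- function(path, geom = NULL) {
  d <- readr::read_delim(path, delim = delim_for(path),
                         show_col_types = FALSE, progress = FALSE)
  req <- c("subject_id", "trial_id", "t", "x", "y")
  if (!all(req %in% names(d))) {
    abort(paste("sample file must have columns", paste(req, collapse = ", ")))
  }
  if (!"valid" %in% names(d)) d$valid <- TRUE
  d$valid <- as.logical(d$valid)
  if (!is.null(geom)) {
    xy <- px_to_dva(cbind(d$x, d$y), geom)
    d$x <- xy[, 1]; d$y <- xy[, 2]
  }
  d
}

#' @rdname gaze_io
#' @param samples Sample tibble to write.
#' @export
write_gaze_samples <- function(samples, path) {
  readr::write_delim(samples, path, delim = delim_for(path), progress = FALSE)
  invisible(path)
}

#' @rdname gaze_io
#' @export
read_gaze_events <- function(path) {
  d <- readr::read_delim(path, delim = delim_for(path),
                         show_col_types = FALSE, progress = FALSE)
  req <- c("subject_id", "trial_id", "kind", "onset", "offset")
  if (!all(req %in% names(d))) {
    abort(paste("event file must have columns", paste(req, collapse = ", ")))
  }
  if (!"duration" %in% names(d)) d$duration <- d$offset - d$onset
  if (!"flags" %in% names(d)) d$flags <- ""
  d$flags[is.na(d$flags)] <- ""
  d
}

#' @rdname gaze_io
#' @param events Event tibble to write.
#' @export
write_gaze_events <- function(events, path) {
  readr::write_delim(events, path, delim = delim_for(path), progress = FALSE)
  invisible(path)
}

#' Read vendor-parsed events from an EyeLink-ASC-style text file
#'
#' Parses `EFIX`, `ESACC` and `EBLINK` end-of-event records from an ASC-style
#' log. Trials are delimited by `MSG <time> TRIALID <id>` lines; event times
#' are re-based to the trial's TRIALID timestamp. Coordinates in the file
#' are screen pixels and are converted to dva with `geom`. This mirrors the
#' use of vendor-parsed events in place of [detect_events()].
#'
#' @param path ASC-style text file.
#' @param geom A [screen_geometry()] for the pixel-to-dva conversion.
#' @param subject_id Subject identifier attached to all events.
#' @return An event tibble in the [detect_events()] schema.
#' @export
read_asc_events <- function(path, geom, subject_id = "s1") {
  lines <- readLines(path, warn = FALSE)
  trial <- NA_character_
  t0 <- 0
  rows <- list()
  for (ln in lines) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) == 0) next
    if (f[1] == "MSG" && length(f) >= 4 && f[3] == "TRIALID") {
      trial <- f[4]
      t0 <- as.numeric(f[2])
    } else if (f[1] == "EFIX" && length(f) >= 7) {
      v <- as.numeric(f[3:7])
      p <- unname(px_to_dva(c(v[4], v[5]), geom))
      rows[[length(rows) + 1]] <- tibble::tibble(
        trial_id = trial, kind = "fixation",
        onset = v[1] - t0, offset = v[2] - t0, duration = v[3],
        x_start = p[1], y_start = p[2], x_end = p[1], y_end = p[2],
        x_mean = p[1], y_mean = p[2],
        amplitude = NA_real_, peak_velocity = NA_real_)
    } else if (f[1] == "ESACC" && length(f) >= 11) {
      v <- as.numeric(f[3:11])
      s <- unname(px_to_dva(c(v[4], v[5]), geom))
      e <- unname(px_to_dva(c(v[6], v[7]), geom))
      rows[[length(rows) + 1]] <- tibble::tibble(
        trial_id = trial, kind = "saccade",
        onset = v[1] - t0, offset = v[2] - t0, duration = v[3],
        x_start = s[1], y_start = s[2], x_end = e[1], y_end = e[2],
        x_mean = (s[1] + e[1]) / 2, y_mean = (s[2] + e[2]) / 2,
        amplitude = v[8], peak_velocity = v[9])
    } else if (f[1] == "EBLINK" && length(f) >= 5) {
      v <- as.numeric(f[3:5])
      rows[[length(rows) + 1]] <- tibble::tibble(
        trial_id = trial, kind = "blink",
        onset = v[1] - t0, offset = v[2] - t0, duration = v[3],
        x_start = NA_real_, y_start = NA_real_, x_end = NA_real_,
        y_end = NA_real_, x_mean = NA_real_, y_mean = NA_real_,
        amplitude = NA_real_, peak_velocity = NA_real_)
    }
  }
  if (length(rows) == 0) return(empty_events())
  ev <- dplyr::bind_rows(rows)
  ev$subject_id <- subject_id
  ev$flags <- ""
  dplyr::relocate(ev, "subject_id")
}
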