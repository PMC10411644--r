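#' Exclusion cascade for oculomotor event tables
#'
#' Events are never deleted: each rule appends its identifier to the
#' semicolon-joined `flags` column, so retained events are those with an
#' empty flag set and every exclusion is auditable. All thresholds are
#' strict inequalities; values exactly at a boundary are retained.
#'
#' Rules (applied by [apply_cascade()] in this order):
#' \describe{
#'   \item{early_onset}{onset < 100 ms trial time (events initiated before
#'     or around image onset).}
#'   \item{short_fixation}{fixations with duration < 100 ms.}
#'   \item{blink_adjacent}{events whose span intersects a window from
#'     100 ms before a blink onset to 100 ms after its offset.}
#'   \item{corrective}{saccades smaller than 30% of the nearest preceding
#'     retained saccade with a relative angle < 20 deg (same-directed) or
#'     > 160 deg (opposite-directed).}
#'   \item{over_duration / over_velocity}{duration > 1,000 ms; saccadic
#'     peak velocity > 1,000 deg/s.}
#'   \item{off_image}{reference coordinates outside the closed image
#'     rectangle (fixations: mean position; saccades: start or landing
#'     point).}
#' }
#'
#' @param events Event tibble (see [detect_events()]).
#' @param onset_min Trial-time onset criterion, ms.
#' @name exclusion_cascade
NULL

add_flag <- function(events, hit, rule) {
  hit <- hit & !is.na(hit)
  already <- flag_hits(events$flags, rule)
  hit <- hit & !already
  events$flags[hit] <- ifelse(events$flags[hit] == "", rule,
                              paste(events$flags[hit], rule, sep = ";"))
  events
}

flag_hits <- function(flags, rule) {
  vapply(strsplit(flags, ";", fixed = TRUE),
         function(f) rule %in% f, logical(1))
}

is_retained <- function(events) events$flags == ""

#' @rdname exclusion_cascade
#' @export
flag_early_onset <- function(events, onset_min = 100) {
  add_flag(events, events$onset < onset_min, "early_onset")
}

#' @rdname exclusion_cascade
#' @param duration_min Minimum fixation duration, ms.
#' @export
flag_short_fixations <- function(events, duration_min = 100) {
  add_flag(events, events$kind == "fixation" & events$duration < duration_min,
           "short_fixation")
}

#' @rdname exclusion_cascade
#' @param blinks Blink events; defaults to the blink rows of `events`.
#' @param window Guard window around each blink, ms.
#' @export
flag_blink_adjacent <- function(events, blinks = NULL, window = 100) {
  if (is.null(blinks)) blinks <- events[events$kind == "blink", , drop = FALSE]
  if (nrow(blinks) == 0) return(events)
  hit <- rep(FALSE, nrow(events))
  keys <- paste(events$subject_id, events$trial_id)
  bkeys <- paste(blinks$subject_id, blinks$trial_id)
  ev_by_key <- split(seq_len(nrow(events)), keys)
  bl_by_key <- split(seq_len(nrow(blinks)), bkeys)
  for (key in names(bl_by_key)) {
    ei <- ev_by_key[[key]]
    if (is.null(ei)) next
    for (bi in bl_by_key[[key]]) {
      lo <- blinks$onset[bi] - window
      hi <- blinks$offset[bi] + window
      hit[ei] <- hit[ei] | (events$kind[ei] != "blink" &
                              events$onset[ei] < hi & events$offset[ei] > lo)
    }
  }
  add_flag(events, hit, "blink_adjacent")
}

#' Test whether a saccade is corrective relative to its predecessor
#'
#' A corrective saccade is a small follow-up saccade: amplitude strictly
#' below 30% of the preceding saccade's amplitude, with a relative angle
#' strictly below 20 degrees (same-directed) or strictly above 160 degrees
#' (opposite-directed).
#'
#' @param prev_saccade,saccade One-row saccade event tibbles.
#' @param amp_frac Amplitude fraction criterion.
#' @param angle_same,angle_opposite Angular criteria in degrees.
#' @return Logical scalar.
#' @export
is_corrective <- function(prev_saccade, saccade, amp_frac = 0.30,
                          angle_same = 20, angle_opposite = 160) {
  if (is.na(prev_saccade$amplitude) || prev_saccade$amplitude == 0) {
    warn("zero-amplitude preceding saccade: corrective test is false")
    return(FALSE)
  }
  if (is.na(saccade$amplitude) || saccade$amplitude == 0) return(FALSE)
  ang <- relative_angle(prev_saccade, saccade)
  saccade$amplitude < amp_frac * prev_saccade$amplitude &&
    (ang < angle_same || ang > angle_opposite)
}

#' @rdname exclusion_cascade
#' @param amp_frac,angle_same,angle_opposite Corrective-saccade criteria,
#'   see [is_corrective()].
#' @export
flag_corrective <- function(events, amp_frac = 0.30, angle_same = 20,
                            angle_opposite = 160) {
  keys <- paste(events$subject_id, events$trial_id)
  hit <- rep(FALSE, nrow(events))
  is_sacc <- events$kind == "saccade"
  amp <- events$amplitude
  dx <- events$x_end - events$x_start
  dy <- events$y_end - events$y_start
  nrm <- sqrt(dx^2 + dy^2)
  flagged <- events$flags != ""
  onset <- events$onset
  cs <- cos(c(angle_same, angle_opposite) * pi / 180)
  by_key <- split(which(is_sacc), keys[is_sacc])
  for (idx in by_key) {
    idx <- idx[order(onset[idx])]
    prev <- NA_integer_
    for (i in idx) {
      if (!is.na(prev) && !flagged[i] &&
          !is.na(amp[prev]) && amp[prev] > 0 && !is.na(amp[i]) && amp[i] > 0 &&
          nrm[prev] > 0 && nrm[i] > 0) {
        cosv <- (dx[prev] * dx[i] + dy[prev] * dy[i]) / (nrm[prev] * nrm[i])
        # angle < angle_same  <=>  cos > cos(angle_same); reversal likewise
        if (amp[i] < amp_frac * amp[prev] && (cosv > cs[1] || cosv < cs[2])) {
          hit[i] <- TRUE
        }
      }
      # the nearest preceding *retained* saccade; flagged ones are skipped
      if (!flagged[i] && !hit[i]) prev <- i
    }
  }
  add_flag(events, hit, "corrective")
}

#' @rdname exclusion_cascade
#' @param duration_max Maximum event duration, ms.
#' @param velocity_max Maximum saccadic peak velocity, deg/s.
#' @export
flag_over_limits <- function(events, duration_max = 1000,
                             velocity_max = 1000) {
  events <- add_flag(events, events$duration > duration_max, "over_duration")
  add_flag(events,
           events$kind == "saccade" & events$peak_velocity > velocity_max,
           "over_velocity")
}

#' @rdname exclusion_cascade
#' @param geom A [screen_geometry()]; the image spans
#'   `[0, width_dva] x [0, height_dva]` (closed boundary retained).
#' @export
flag_off_image <- function(events, geom) {
  w <- geom$width_dva; h <- geom$height_dva
  out_pt <- function(x, y) !is.na(x) & (x < 0 | x > w | y < 0 | y > h)
  hit <- ifelse(events$kind == "fixation",
                out_pt(events$x_mean, events$y_mean),
                out_pt(events$x_start, events$y_start) |
                  out_pt(events$x_end, events$y_end))
  hit[events$kind == "blink"] <- FALSE
  add_flag(events, hit, "off_image")
}

#' Apply the full exclusion cascade
#'
#' Runs all rules in their documented order (early_onset, short_fixation,
#' blink_adjacent, corrective, over_duration/over_velocity, off_image).
#' Only the corrective rule is order-dependent: it looks for the nearest
#' preceding saccade not yet flagged by an earlier rule.
#'
#' @inheritParams exclusion_cascade
#' @param geom A [screen_geometry()] for the off-image rule; `NULL` skips it.
#' @param blinks Optional separate blink table; defaults to blink rows of
#'   `events`.
#' @return The event tibble with populated `flags`. The per-rule summary is
#'   available via [exclusion_report()].
#' @export
apply_cascade <- function(events, geom = NULL, blinks = NULL) {
  events <- flag_early_onset(events)
  events <- flag_short_fixations(events)
  events <- flag_blink_adjacent(events, blinks)
  events <- flag_corrective(events)
  events <- flag_over_limits(events)
  if (!is.null(geom)) events <- flag_off_image(events, geom)
  events
}

#' Per-rule exclusion summary
#'
#' Counts and fractions of flagged events per rule, both pooled over all
#' events and as the mean of per-subject fractions (flags may overlap, so
#' rule rows need not sum to the union row `any`).
#'
#' @param events Flagged event tibble from [apply_cascade()].
#' @return Tibble with `rule_id`, `n_flagged`, `fraction` (pooled) and
#'   `fraction_subject_mean`.
#' @export
exclusion_report <- function(events) {
  rules <- c("early_onset", "short_fixation", "blink_adjacent", "corrective",
             "over_duration", "over_velocity", "off_image")
  n <- nrow(events)
  subj <- events$subject_id
  per_rule <- lapply(c(rules, "any"), function(r) {
    hit <- if (r == "any") events$flags != "" else flag_hits(events$flags, r)
    by_subj <- tapply(hit, subj, mean)
    tibble::tibble(rule_id = r, n_flagged = sum(hit),
                   fraction = if (n > 0) sum(hit) / n else 0,
                   fraction_subject_mean =
                     if (n > 0) mean(by_subj) else 0)
  })
  dplyr::bind_rows(per_rule)
}

#' Write an exclusion report as TSV and JSON
#'
#' @param report Tibble from [exclusion_report()].
#' @param path_tsv,path_json Output paths (either may be `NULL`).
#' @export
write_exclusion_report <- function(report, path_tsv = NULL, path_json = NULL) {
  if (!is.null(path_tsv)) {
    readr::write_tsv(report, path_tsv, progress = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(report, path_json, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
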