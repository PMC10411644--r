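#' Segment a gaze sample stream into saccades, fixations and blinks
#'
#' Velocity-and-acceleration based event segmentation. Sample-to-sample
#' velocity is estimated with central differences and smoothed with a
#' centred 5-sample moving average before thresholding; acceleration is the
#' central difference of the smoothed speed. A saccade starts where smoothed
#' speed exceeds `vel_thresh` or |acceleration| exceeds `acc_thresh`, and
#' ends only when both stay below their thresholds for at least
#' `min_below` consecutive samples (hysteresis, so velocity jitter near
#' threshold does not split a saccade). Runs of invalid samples (lid
#' occlusion) become blink events and break fixation/saccade runs. Every
#' sample belongs to exactly one event; a candidate saccade whose peak
#' smoothed speed never reaches `vel_thresh` is demoted to fixation, so a
#' detected saccade always satisfies `peak_velocity >= vel_thresh`.
#'
#' @param samples Tibble of gaze samples with columns `subject_id`,
#'   `trial_id`, `t` (ms, strictly increasing within trial, constant
#'   sampling interval), `x`, `y` (dva) and optionally `valid` (logical,
#'   `FALSE` during blinks) and `image_id` (carried through).
#' @param vel_thresh Saccade velocity criterion, deg/s.
#' @param acc_thresh Saccade acceleration criterion, deg/s^2.
#' @param min_below Consecutive sub-threshold samples required to end a
#'   saccade.
#' @param smooth_n Moving-average window (samples) for speed smoothing.
#' @return An event tibble, one row per event, time-ordered within trial:
#'   columns `subject_id`, `trial_id`, (`image_id`,) `kind`
#'   ("saccade"/"fixation"/"blink"), `onset`, `offset`, `duration` (ms),
#'   `x_start`, `y_start`, `x_end`, `y_end`, `x_mean`, `y_mean`,
#'   `amplitude` (dva, saccades), `peak_velocity` (deg/s, saccades) and an
#'   empty `flags` column for the exclusion cascade.
#' @export
detect_events <- function(samples, vel_thresh = 30, acc_thresh = 8000,
                          min_below = 2, smooth_n = 5) {
  req <- c("subject_id", "trial_id", "t", "x", "y")
  if (!all(req %in% names(samples))) {
    abort(paste("samples must have columns", paste(req, collapse = ", ")))
  }
  if (!"valid" %in% names(samples)) samples$valid <- TRUE
  has_img <- "image_id" %in% names(samples)

  keys <- paste(samples$subject_id, samples$trial_id, sep = "\r")
  parts <- split(seq_len(nrow(samples)), factor(keys, levels = unique(keys)))
  out <- lapply(parts, function(idx) {
    tr <- samples[idx, , drop = FALSE]
    ev <- detect_events_trial(tr$t, tr$x, tr$y, tr$valid,
                              vel_thresh, acc_thresh, min_below, smooth_n)
    if (nrow(ev) == 0) return(ev)
    ev$subject_id <- tr$subject_id[1]
    ev$trial_id <- tr$trial_id[1]
    if (has_img) ev$image_id <- tr$image_id[1]
    ev
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(empty_events(has_img))
  }
  front <- c("subject_id", "trial_id", if (has_img) "image_id")
  res <- dplyr::relocate(res, dplyr::all_of(front))
  res$flags <- ""
  tibble::as_tibble(res)
}

empty_events <- function(has_img = FALSE) {
  tb <- tibble::tibble(
    subject_id = character(), trial_id = character(),
    kind = character(), onset = double(), offset = double(),
    duration = double(), x_start = double(), y_start = double(),
    x_end = double(), y_end = double(), x_mean = double(),
    y_mean = double(), amplitude = double(), peak_velocity = double(),
    flags = character()
  )
  if (has_img) tb <- dplyr::mutate(tb, image_id = character(),
                                   .after = "trial_id")
  tb
}

detect_events_trial <- function(t, x, y, valid, vel_thresh, acc_thresh,
                                min_below, smooth_n) {
  n <- length(t)
  if (n < 2) {
    warn("trial with fewer than 2 samples: no events returned")
    return(tibble::tibble())
  }
  dts <- diff(t)
  if (any(dts <= 0)) abort("sample times must be strictly increasing within a trial")
  dt <- median(dts)

  raw_speed <- raw_sample_speed(t, x, y)
  speed <- moving_average(raw_speed, smooth_n)
  accel <- central_diff(speed, t)

  sacc <- (speed > vel_thresh) | (abs(accel) > acc_thresh)

  # blink runs split the trial; segment each valid stretch independently
  state <- ifelse(valid, ifelse(sacc, 1L, 0L), 2L)
  runs <- rle(state)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L

  # hysteresis within valid stretches: absorb short sub-threshold gaps
  # (< min_below samples) flanked by saccade runs
  k <- length(runs$values)
  if (k >= 3) {
    for (i in 2:(k - 1)) {
      if (runs$values[i] == 0L && runs$lengths[i] < min_below &&
          runs$values[i - 1] == 1L && runs$values[i + 1] == 1L) {
        runs$values[i] <- 1L
      }
    }
  }
  state <- inverse.rle(runs)

  # demote candidate saccades that never reach the velocity criterion
  runs <- rle(state)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (i in seq_along(runs$values)) {
    if (runs$values[i] == 1L &&
        max(speed[starts[i]:ends[i]]) < vel_thresh) {
      runs$values[i] <- 0L
    }
  }
  state <- inverse.rle(runs)

  # centred smoothing smears the above-threshold region outward by up to
  # half the window; refine saccade boundaries to the nearest sample where
  # the raw signal still meets either detection criterion (bounded walk)
  # for sample-precision onsets/offsets
  raw_accel <- central_diff(raw_speed, t)
  state <- refine_boundaries(state, raw_speed, raw_accel,
                             vel_thresh, acc_thresh, smooth_n)

  runs <- rle(state)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  kind <- c("fixation", "saccade", "blink")[runs$values + 1L]

  onset <- t[starts]
  offset <- c(t[starts[-1]], t[n] + dt)
  sa <- starts
  en <- ends
  amp <- sqrt((x[en] - x[sa])^2 + (y[en] - y[sa])^2)
  pv <- vapply(seq_along(sa),
               function(i) max(speed[sa[i]:en[i]]), numeric(1))
  tibble::tibble(
    kind = kind, onset = onset, offset = offset, duration = offset - onset,
    x_start = x[sa], y_start = y[sa], x_end = x[en], y_end = y[en],
    x_mean = vapply(seq_along(sa), function(i) mean(x[sa[i]:en[i]]), numeric(1)),
    y_mean = vapply(seq_along(sa), function(i) mean(y[sa[i]:en[i]]), numeric(1)),
    amplitude = ifelse(kind == "saccade", amp, NA_real_),
    peak_velocity = ifelse(kind == "saccade", pv, NA_real_)
  )
}

# central-difference speed, deg/s
raw_sample_speed <- function(t, x, y) {
  vx <- central_diff(x, t)
  vy <- central_diff(y, t)
  sqrt(vx^2 + vy^2)
}

# raw speed smoothed with a centred moving average; window edges use the
# shrunken window so no samples are lost
smoothed_speed <- function(t, x, y, smooth_n = 5) {
  moving_average(raw_sample_speed(t, x, y), smooth_n)
}

# walk each saccade run's edges (at most `limit` samples, never across a
# blink or another saccade) to the nearest sample where the raw speed or
# raw acceleration still meets its detection criterion
refine_boundaries <- function(state, raw_speed, raw_accel,
                              vel_thresh, acc_thresh, limit) {
  # trimming stops where the raw signal still meets either criterion;
  # acceleration only counts while the speed is still clearly elevated,
  # so accel adjacency just outside a sharp-onset saccade (where the
  # speed support has already ended) does not arrest the walk. Extension
  # follows the raw speed alone.
  hot <- raw_speed > vel_thresh |
    (abs(raw_accel) > acc_thresh & raw_speed > vel_thresh / 3)
  fast <- raw_speed > vel_thresh
  runs <- rle(state)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  n <- length(state)
  out <- state
  for (i in which(runs$values == 1L)) {
    s <- starts[i]; e <- ends[i]
    if (hot[s]) {
      k <- 0
      while (s > 1 && k < limit && state[s - 1] == 0L && fast[s - 1]) {
        s <- s - 1; k <- k + 1
      }
    } else {
      k <- 0
      while (s < e && k < limit && !hot[s]) { s <- s + 1; k <- k + 1 }
    }
    if (hot[e]) {
      k <- 0
      while (e < n && k < limit && state[e + 1] == 0L && fast[e + 1]) {
        e <- e + 1; k <- k + 1
      }
    } else {
      k <- 0
      while (e > s && k < limit && !hot[e]) { e <- e - 1; k <- k + 1 }
    }
    if (e > s) {
      out[starts[i]:ends[i]] <- 0L
      out[s:e] <- 1L
    }
  }
  out
}

central_diff <- function(v, t) {
  n <- length(v)
  d <- numeric(n)
  if (n == 1) return(d)
  d[1] <- (v[2] - v[1]) / (t[2] - t[1])
  d[n] <- (v[n] - v[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    d[i] <- (v[i + 1] - v[i - 1]) / (t[i + 1] - t[i - 1])
  }
  d * 1000 # per ms -> per s
}

moving_average <- function(v, n) {
  if (n <= 1 || length(v) < 2) return(v)
  if (length(v) <= n) { # shrunken windows throughout
    half <- (n - 1) %/% 2
    return(vapply(seq_along(v), function(i) {
      mean(v[max(1, i - half):min(length(v), i + half)])
    }, numeric(1)))
  }
  kern <- rep(1, n)
  num <- stats::filter(v, kern, sides = 2)
  den <- stats::filter(rep(1, length(v)), kern, sides = 2)
  out <- as.numeric(num / den)
  # shrunken windows at the edges
  half <- (n - 1) %/% 2
  for (i in seq_len(min(half, length(v)))) {
    w <- max(1, i - half):min(length(v), i + half)
    out[i] <- mean(v[w])
    j <- length(v) - i + 1
    w <- max(1, j - half):min(length(v), j + half)
    out[j] <- mean(v[w])
  }
  out
}

#' Recompute amplitude and peak velocity of a saccade from samples
#'
#' Amplitude is the Euclidean start-to-end displacement (dva); peak
#' velocity is the maximum smoothed sample-to-sample speed within the
#' event, using the same velocity estimator as [detect_events()].
#'
#' @param event A one-row event tibble with `kind == "saccade"`, `onset`
#'   and `offset` (ms).
#' @param samples The trial's samples covering `[onset, offset)`.
#' @param smooth_n Moving-average window, as in [detect_events()].
#' @return A named list with `amplitude` and `peak_velocity`.
#' @export
saccade_metrics <- function(event, samples, smooth_n = 5) {
  if (nrow(event) != 1 || event$kind != "saccade") {
    abort("saccade_metrics expects a single saccade event")
  }
  keep <- samples$t >= event$onset & samples$t < event$offset
  if (sum(keep) < 2) abort("samples do not cover the event span")
  tr <- samples[keep, , drop = FALSE]
  dt <- median(diff(tr$t))
  if (min(tr$t) > event$onset + dt || max(tr$t) < event$offset - 2 * dt) {
    abort("samples do not cover the event span")
  }
  sp <- smoothed_speed(tr$t, tr$x, tr$y, smooth_n)
  n <- nrow(tr)
  list(
    amplitude = sqrt((tr$x[n] - tr$x[1])^2 + (tr$y[n] - tr$y[1])^2),
    peak_velocity = max(sp)
  )
}

#' Absolute angle between two saccade direction vectors
#'
#' The angle (degrees, in \[0, 180\]) between the start-to-end direction of
#' an incoming and a target saccade: 0 denotes a continuation of the
#' incoming direction, 180 a full reversal.
#'
#' @param incoming,target Either one-row saccade event tibbles (columns
#'   `x_start`, `y_start`, `x_end`, `y_end`) or length-2 direction vectors
#'   `c(dx, dy)`.
#' @return Angle in degrees within \[0, 180\].
#' @export
relative_angle <- function(incoming, target) {
  d1 <- as_direction(incoming)
  d2 <- as_direction(target)
  rel_angle_vec(d1[1], d1[2], d2[1], d2[2])
}

as_direction <- function(obj) {
  if (is.data.frame(obj)) {
    if (nrow(obj) != 1) abort("expected a single event row")
    c(obj$x_end - obj$x_start, obj$y_end - obj$y_start)
  } else {
    if (length(obj) != 2) abort("expected a length-2 direction vector")
    as.double(obj)
  }
}

# vectorised angle between direction vectors, degrees in [0, 180]
rel_angle_vec <- function(dx1, dy1, dx2, dy2) {
  n1 <- sqrt(dx1^2 + dy1^2)
  n2 <- sqrt(dx2^2 + dy2^2)
  if (any(n1 == 0 | n2 == 0)) {
    abort("relative angle undefined for a zero-amplitude saccade")
  }
  cosv <- pmin(1, pmax(-1, (dx1 * dx2 + dy1 * dy2) / (n1 * n2)))
  acos(cosv) * 180 / pi
}
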