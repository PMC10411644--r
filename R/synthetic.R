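#' Configuration for the synthetic free-viewing scanpath generator
#'
#' The generator emulates the statistical structure the analysis assumes:
#' 3-second trials, every subject viewing every image, saccadic peak
#' velocity following a saturating-exponential main sequence
#' `v_max * (1 - exp(-A / c))`, right-skewed (log-normal) fixation
#' durations with linear dependencies on trial time, relative angle and
#' incoming amplitude, direction persistence of successive saccades, and
#' planted face-target effects on peak velocity and on the duration of the
#' fixation preceding a face-directed saccade. Planted effects are
#' expressed in standard-deviation units of the (z-scored) response so
#' recovered standardized betas compare directly to the planted values.
#'
#' The full-study scale is 101 subjects by 700 images; the defaults are the
#' study conditions, and smaller sizes are set per call for test work.
#' Synthetic scenes are rasterized at 320 x 240 px — mask resolution only
#' sets the granularity of disc overlap, not the dva geometry, which is
#' always the full 29.7 x 22.3 image.
#'
#' @param n_subjects,n_images Design size (all subjects see all images).
#' @param trial_ms Trial duration, ms.
#' @param sample_hz Sampling rate for rendered streams.
#' @param image_px Raster size `c(width, height)` of synthetic masks.
#' @param main_sequence List `v_max` (deg/s) and `c` (dva), the saturation
#'   constants of the peak-velocity/amplitude law.
#' @param face_velocity_boost Planted face-target effect on peak velocity,
#'   SD units.
#' @param velocity_sigma Residual velocity noise, deg/s.
#' @param velocity_onset_slope Trial-time effect on velocity, SD units per
#'   SD of onset time.
#' @param duration_model List: log-normal `meanlog`/`sdlog` (log-ms),
#'   `face_shortening` (SD units, negative shortens), and `onset_slope`,
#'   `angle_slope`, `incoming_amplitude_slope` (SD units per SD).
#' @param direction_persistence Probability that a saccade continues the
#'   previous direction (picks the direction-preserving candidate target).
#' @param scene_layout List: `n_objects` per image, per-object label
#'   probabilities `face_prob`, `body_prob`, `animal_prob` (remainder
#'   inanimate), and `size_range` (% image area per object).
#' @param random_effect_sds Named vector `subject`, `image`, `object`
#'   (SD units, applied to both responses with independent draws).
#' @param object_bias Probability a fixation targets an object rather than
#'   background.
#' @param artifact_rates Per-step probabilities exercising the exclusion
#'   cascade: `corrective` (planted corrective saccades), `blink`,
#'   `over_velocity`, `over_duration`.
#' @param seed Integer seed; a fixed seed gives bit-identical output.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_subjects = 101, n_images = 700, trial_ms = 3000,
                         sample_hz = 2000, image_px = c(320, 240),
                         main_sequence = list(v_max = 500, c = 8),
                         face_velocity_boost = 0.07,
                         velocity_sigma = 30,
                         velocity_onset_slope = 0.02,
                         duration_model = list(
                           meanlog = 5.3, sdlog = 0.45,
                           face_shortening = -0.08,
                           onset_slope = 0.18, angle_slope = 0.12,
                           incoming_amplitude_slope = 0.11),
                         direction_persistence = 0.4,
                         scene_layout = list(
                           n_objects = 8, face_prob = 0.12,
                           body_prob = 0.10, animal_prob = 0.04,
                           size_range = c(1, 6)),
                         random_effect_sds = c(subject = 0.10,
                                               image = 0.05,
                                               object = 0.05),
                         object_bias = 0.85,
                         artifact_rates = c(corrective = 0.02,
                                            blink = 0.03,
                                            over_velocity = 0.002,
                                            over_duration = 0.002),
                         seed = 1L) {
  probs <- c(direction_persistence, object_bias, artifact_rates,
             scene_layout$face_prob, scene_layout$body_prob,
             scene_layout$animal_prob)
  if (any(probs < 0 | probs > 1)) abort("rates/probabilities must be in [0, 1]")
  pos <- c(n_subjects, n_images, trial_ms, sample_hz, image_px,
           main_sequence$v_max, main_sequence$c, velocity_sigma,
           duration_model$sdlog, scene_layout$n_objects,
           scene_layout$size_range)
  if (any(pos <= 0)) abort("scale parameters must be positive")
  structure(
    list(n_subjects = n_subjects, n_images = n_images, trial_ms = trial_ms,
         sample_hz = sample_hz, image_px = image_px,
         main_sequence = main_sequence,
         face_velocity_boost = face_velocity_boost,
         velocity_sigma = velocity_sigma,
         velocity_onset_slope = velocity_onset_slope,
         duration_model = duration_model,
         direction_persistence = direction_persistence,
         scene_layout = scene_layout,
         random_effect_sds = random_effect_sds,
         object_bias = object_bias, artifact_rates = artifact_rates,
         seed = as.integer(seed)),
    class = "synth_config")
}

synth_geom <- function(cfg) {
  screen_geometry(cfg$image_px[1], cfg$image_px[2])
}

#' Generate synthetic annotated scenes
#'
#' Places non-overlapping rectangular or elliptical object masks with
#' semantic labels and builds a synthetic saliency map per image (Gaussian
#' blobs centered on the objects over a low baseline, scaled so foveation
#' disc sums land in a 0-400 a.u. range). Objects are separated by a
#' margin wider than the 0.5 dva foveation radius so disc labels are
#' unambiguous.
#'
#' @param cfg A [synth_config()].
#' @return List with `annotations` and `saliency`, both named by image id,
#'   and `geom`.
#' @export
generate_scenes <- function(cfg) {
  set.seed(cfg$seed)
  geom <- synth_geom(cfg)
  lay <- cfg$scene_layout
  W <- geom$width_px; H <- geom$height_px
  margin_px <- ceiling(0.6 * geom$px_per_dva_x) # > foveation radius
  img_ids <- sprintf("img%04d", seq_len(cfg$n_images))

  annots <- vector("list", cfg$n_images)
  sal <- vector("list", cfg$n_images)
  p_inan <- 1 - lay$face_prob - lay$body_prob - lay$animal_prob
  if (p_inan < 0) abort("label probabilities exceed 1")
  for (i in seq_len(cfg$n_images)) {
    cats <- sample(c("face", "body", "animal", "inanimate"), lay$n_objects,
                   replace = TRUE,
                   prob = c(lay$face_prob, lay$body_prob, lay$animal_prob,
                            p_inan))
    placed_all <- FALSE
    for (attempt in seq_len(20)) {
      lm <- matrix(0L, H, W)
      boxes <- matrix(0, 0, 4) # x0 y0 x1 y1, px
      centers <- matrix(0, lay$n_objects, 2)
      shapes <- sample(c("rect", "ellipse"), lay$n_objects, replace = TRUE)
      areas <- runif(lay$n_objects, lay$size_range[1], lay$size_range[2])
      ord <- order(areas, decreasing = TRUE) # large objects placed first
      ok <- TRUE
      for (j in ord) {
        area_px <- areas[j] / 100 * W * H
        aspect <- runif(1, 0.6, 1.6)
        hw <- max(2, round(sqrt(area_px * aspect) / 2))
        hh <- max(2, round(sqrt(area_px / aspect) / 2))
        placed <- FALSE
        for (try in seq_len(200)) {
          cx <- round(runif(1, hw + 1, W - hw - 1))
          cy <- round(runif(1, hh + 1, H - hh - 1))
          box <- c(cx - hw - margin_px, cy - hh - margin_px,
                   cx + hw + margin_px, cy + hh + margin_px)
          clash <- nrow(boxes) > 0 &&
            any(boxes[, 1] <= box[3] & boxes[, 3] >= box[1] &
                  boxes[, 2] <= box[4] & boxes[, 4] >= box[2])
          if (!clash) {
            rows <- (cy - hh):(cy + hh); cols <- (cx - hw):(cx + hw)
            if (shapes[j] == "rect") {
              lm[rows, cols] <- j
            } else {
              rr <- outer(((rows - cy) / hh)^2, ((cols - cx) / hw)^2, `+`)
              sub <- lm[rows, cols]; sub[rr <= 1] <- j
              lm[rows, cols] <- sub
            }
            boxes <- rbind(boxes, box)
            centers[j, ] <- c(cx, cy)
            placed <- TRUE
            break
          }
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) { placed_all <- TRUE; break }
    }
    if (!placed_all) abort("infeasible scene layout: objects cannot be placed")
    labels <- lapply(cats, function(cat) switch(cat,
      face = c("inner_face", "head", "person"),
      body = c("body", "person"),
      animal = "animal",
      inanimate = "inanimate_object"))
    annot <- scene_annotation(img_ids[i], geom, labels = labels,
                              label_mat = lm)
    annot$centers_dva <- cbind(centers[, 1] / geom$px_per_dva_x,
                               centers[, 2] / geom$px_per_dva_y)
    annot$half_dva <- cbind(
      vapply(seq_len(lay$n_objects), function(j)
        (max(which(colSums(lm == j) > 0)) -
           min(which(colSums(lm == j) > 0))) / 2 / geom$px_per_dva_x,
        numeric(1)),
      vapply(seq_len(lay$n_objects), function(j)
        (max(which(rowSums(lm == j) > 0)) -
           min(which(rowSums(lm == j) > 0))) / 2 / geom$px_per_dva_y,
        numeric(1)))
    annot$category <- cats
    annots[[i]] <- annot

    sv <- matrix(0.5, H, W)
    for (j in seq_len(lay$n_objects)) {
      sg <- max(3, (annot$half_dva[j, 1] * geom$px_per_dva_x))
      gx <- exp(-(seq_len(W) - centers[j, 1])^2 / (2 * sg^2))
      gy <- exp(-(seq_len(H) - centers[j, 2])^2 / (2 * sg^2))
      sv <- sv + 3 * outer(gy, gx) # separable Gaussian blob
    }
    sal[[i]] <- saliency_map(img_ids[i], sv, geom)
  }
  list(annotations = stats::setNames(annots, img_ids),
       saliency = stats::setNames(sal, img_ids),
       geom = geom)
}

#' Generate synthetic gaze event tables with ground truth
#'
#' Simulates, per trial, a chain of fixations on scene objects (or
#' background) and connecting saccades. Successive saccade directions
#' persist with the configured probability; fixation durations are
#' log-normal with linear terms in trial time, relative angle and
#' incoming amplitude; peak velocity follows the saturating main sequence
#' plus noise and random effects. The planted face effects are applied on
#' the empirical standardized scale: the velocity boost adds
#' `face_velocity_boost` times the null-model SD of peak velocity to
#' face-directed saccades, and `face_shortening` enters the standardized
#' log-duration predictor of fixations preceding a face-directed saccade.
#' Planted corrective saccades, blinks and over-limit events are injected
#' at the configured rates to exercise the exclusion cascade; the trial's
#' first fixation starts at 0 ms and exercises the early-onset rule.
#'
#' @param cfg A [synth_config()].
#' @param scenes Output of [generate_scenes()] (regenerated if `NULL`).
#' @return List with `events` (the event-table schema of
#'   [detect_events()]), `ground_truth` (planted values and per-saccade
#'   generator log) and `scenes`.
#' @export
generate_gaze <- function(cfg, scenes = NULL) {
  if (is.null(scenes)) scenes <- generate_scenes(cfg)
  set.seed(cfg$seed + 1L)
  geom <- scenes$geom
  S <- cfg$n_subjects; I <- cfg$n_images
  nob <- cfg$scene_layout$n_objects
  Tn <- S * I
  subj_idx <- rep(seq_len(S), each = I)
  img_idx <- rep(seq_len(I), times = S)
  img_ids <- names(scenes$annotations)

  # per-image object geometry as [I, nob] matrices
  ocx <- t(vapply(scenes$annotations, function(a) a$centers_dva[, 1],
                  numeric(nob)))
  ocy <- t(vapply(scenes$annotations, function(a) a$centers_dva[, 2],
                  numeric(nob)))
  ohx <- t(vapply(scenes$annotations, function(a) a$half_dva[, 1],
                  numeric(nob)))
  ohy <- t(vapply(scenes$annotations, function(a) a$half_dva[, 2],
                  numeric(nob)))
  oface <- t(vapply(scenes$annotations,
                    function(a) a$category == "face", logical(nob)))
  oinan <- t(vapply(scenes$annotations,
                    function(a) a$category == "inanimate", logical(nob)))

  re <- cfg$random_effect_sds
  u_subj_v <- rnorm(S, 0, re["subject"]); u_subj_d <- rnorm(S, 0, re["subject"])
  u_img_v <- rnorm(I, 0, re["image"]); u_img_d <- rnorm(I, 0, re["image"])
  u_obj_v <- matrix(rnorm(I * nob, 0, re["object"]), I, nob)
  u_obj_d <- matrix(rnorm(I * nob, 0, re["object"]), I, nob)

  dm <- cfg$duration_model
  slope_var <- dm$onset_slope^2 + dm$angle_slope^2 +
    dm$incoming_amplitude_slope^2
  re_var <- re["subject"]^2 + re["image"]^2 + re["object"]^2
  eps_sd <- sqrt(max(0.1, 1 - slope_var - re_var))

  ar <- cfg$artifact_rates
  w <- geom$width_dva; h <- geom$height_dva
  ms <- cfg$main_sequence

  cur_x <- rep(w / 2, Tn) + runif(Tn, -1, 1)
  cur_y <- rep(h / 2, Tn) + runif(Tn, -1, 1)
  cur_obj <- rep(0L, Tn)
  prev_dx <- rep(NA_real_, Tn); prev_dy <- rep(NA_real_, Tn)
  prev_amp <- rep(NA_real_, Tn)
  t_cur <- rep(0, Tn)
  active <- rep(TRUE, Tn)

  fix_rows <- list(); sac_rows <- list()
  step <- 0L
  while (any(active) && step < 60L) {
    step <- step + 1L
    a <- which(active)
    n <- length(a)
    ii <- img_idx[a]; ss <- subj_idx[a]

    # --- choose the next fixation target --------------------------------
    corr <- runif(n) < ar["corrective"] & !is.na(prev_dx[a])
    on_obj <- runif(n) < cfg$object_bias & !corr
    c1 <- sample.int(nob, n, replace = TRUE)
    c2 <- sample.int(nob, n, replace = TRUE)
    lin1 <- cbind(ii, c1); lin2 <- cbind(ii, c2)
    d1x <- ocx[lin1] - cur_x[a]; d1y <- ocy[lin1] - cur_y[a]
    d2x <- ocx[lin2] - cur_x[a]; d2y <- ocy[lin2] - cur_y[a]
    cos1 <- (d1x * prev_dx[a] + d1y * prev_dy[a]) /
      pmax(sqrt(d1x^2 + d1y^2) * sqrt(prev_dx[a]^2 + prev_dy[a]^2), 1e-9)
    cos2 <- (d2x * prev_dx[a] + d2y * prev_dy[a]) /
      pmax(sqrt(d2x^2 + d2y^2) * sqrt(prev_dx[a]^2 + prev_dy[a]^2), 1e-9)
    persist <- runif(n) < cfg$direction_persistence & !is.na(cos1)
    pick2 <- persist & (cos2 > cos1)
    jc <- ifelse(pick2, c2, c1)
    linj <- cbind(ii, jc)
    tx <- ocx[linj] + runif(n, -0.4, 0.4) * ohx[linj]
    ty <- ocy[linj] + runif(n, -0.4, 0.4) * ohy[linj]
    # background fixations
    bg <- !on_obj & !corr
    tx[bg] <- runif(sum(bg), 0.5, w - 0.5)
    ty[bg] <- runif(sum(bg), 0.5, h - 0.5)
    jc[bg] <- 0L
    # planted corrective saccades: small, nearly same-directed
    if (any(corr)) {
      k <- which(corr)
      th <- atan2(prev_dy[a][k], prev_dx[a][k]) + rnorm(length(k), 0, 0.06)
      amp_c <- 0.15 * prev_amp[a][k]
      tx[k] <- pmin(pmax(cur_x[a][k] + amp_c * cos(th), 0.2), w - 0.2)
      ty[k] <- pmin(pmax(cur_y[a][k] + amp_c * sin(th), 0.2), h - 0.2)
      jc[k] <- 0L
    }
    dx <- tx - cur_x[a]; dy <- ty - cur_y[a]
    A <- pmax(sqrt(dx^2 + dy^2), 0.05)
    face_next <- jc > 0 & oface[cbind(ii, pmax(jc, 1L))]

    # --- current fixation (or blink) duration ---------------------------
    theta <- ifelse(is.na(prev_dx[a]), 90,
                    acos(pmin(1, pmax(-1, (dx * prev_dx[a] + dy * prev_dy[a]) /
                      pmax(A * sqrt(prev_dx[a]^2 + prev_dy[a]^2), 1e-9)))) *
                      180 / pi)
    z_onset <- (t_cur[a] - 1400) / 800
    z_angle <- (theta - 70) / 50
    z_inamp <- ifelse(is.na(prev_amp[a]), 0, (prev_amp[a] - 10) / 5)
    uo_d <- ifelse(jc > 0, u_obj_d[cbind(ii, pmax(jc, 1L))], 0)
    eta <- dm$onset_slope * z_onset + dm$angle_slope * z_angle +
      dm$incoming_amplitude_slope * z_inamp +
      u_subj_d[ss] + u_img_d[ii] + uo_d +
      dm$face_shortening * face_next + rnorm(n, 0, eps_sd)
    dur <- exp(dm$meanlog + dm$sdlog * eta)
    over_d <- runif(n) < ar["over_duration"]
    dur[over_d] <- dur[over_d] + 1200
    blink_here <- runif(n) < ar["blink"] & step > 1L
    dur[blink_here] <- runif(sum(blink_here), 100, 300)

    f_on <- t_cur[a]
    f_off <- pmin(f_on + dur, cfg$trial_ms)
    sdur <- 2.2 * A + 21
    ends <- f_off >= cfg$trial_ms | (f_off + sdur) > cfg$trial_ms
    f_off[ends] <- cfg$trial_ms

    fix_rows[[step]] <- tibble::tibble(
      ti = a, kind = ifelse(blink_here & !ends, "blink", "fixation"),
      onset = f_on, offset = f_off,
      x = cur_x[a], y = cur_y[a])

    # --- target saccade --------------------------------------------------
    go <- !ends
    v0 <- ms$v_max * (1 - exp(-A / ms$c)) + rnorm(n, 0, cfg$velocity_sigma)
    over_v <- runif(n) < ar["over_velocity"]
    v0[over_v] <- v0[over_v] * 3
    if (any(go)) {
      g <- which(go)
      prev_obj <- cur_obj[a][g]
      sac_rows[[step]] <- tibble::tibble(
        ti = a[g], onset = f_off[g], offset = f_off[g] + sdur[g],
        x0 = cur_x[a][g], y0 = cur_y[a][g], x1 = tx[g], y1 = ty[g],
        amp = A[g], v0 = v0[g], face = face_next[g], obj = jc[g],
        prev_obj = prev_obj,
        prev_inan = prev_obj > 0 &
          oinan[cbind(ii[g], pmax(prev_obj, 1L))],
        corrective = corr[g])
    }

    cur_obj[a[go]] <- jc[go]
    cur_x[a[go]] <- tx[go]; cur_y[a[go]] <- ty[go]
    prev_dx[a[go]] <- dx[go]; prev_dy[a[go]] <- dy[go]
    prev_amp[a[go]] <- A[go]
    t_cur[a[go]] <- f_off[go] + sdur[go]
    active[a[!go]] <- FALSE
  }

  fx <- dplyr::bind_rows(fix_rows)
  sc <- dplyr::bind_rows(sac_rows)

  # plant velocity effects on the empirical standardized scale: the
  # reference SD is computed over a proxy of the qualifying series
  # population (object-to-different-object target saccades launched from
  # an inanimate-object fixation, non-corrective, below the velocity
  # limit), which is the population the pipeline z-scores over
  proxy <- sc$obj > 0 & sc$prev_inan & sc$obj != sc$prev_obj &
    !sc$corrective & sc$v0 < 1000
  sd_v <- if (sum(proxy) > 2) sd(sc$v0[proxy]) else sd(sc$v0)
  zo <- (sc$onset - mean(sc$onset)) / sd(sc$onset)
  sc$pv <- sc$v0 + sd_v *
    (cfg$velocity_onset_slope * zo +
       u_subj_v[subj_idx[sc$ti]] + u_img_v[img_idx[sc$ti]] +
       ifelse(sc$obj > 0, u_obj_v[cbind(img_idx[sc$ti], pmax(sc$obj, 1L))], 0) +
       cfg$face_velocity_boost * sc$face)
  sc$pv <- pmax(sc$pv, 31)

  fe <- tibble::tibble(
    ti = fx$ti, kind = fx$kind, onset = fx$onset, offset = fx$offset,
    x_start = fx$x, y_start = fx$y, x_end = fx$x, y_end = fx$y,
    x_mean = fx$x, y_mean = fx$y,
    amplitude = NA_real_, peak_velocity = NA_real_)
  se <- tibble::tibble(
    ti = sc$ti, kind = "saccade", onset = sc$onset, offset = sc$offset,
    x_start = sc$x0, y_start = sc$y0, x_end = sc$x1, y_end = sc$y1,
    x_mean = (sc$x0 + sc$x1) / 2, y_mean = (sc$y0 + sc$y1) / 2,
    amplitude = sc$amp, peak_velocity = sc$pv)
  ev <- dplyr::bind_rows(fe, se)
  ev$subject_id <- sprintf("s%03d", subj_idx[ev$ti])
  ev$image_id <- img_ids[img_idx[ev$ti]]
  ev$trial_id <- ev$image_id
  ev$duration <- ev$offset - ev$onset
  ev$flags <- ""
  ev <- ev[order(ev$subject_id, ev$trial_id, ev$onset), ]
  ev$ti <- NULL
  ev <- dplyr::relocate(tibble::as_tibble(ev),
                        "subject_id", "trial_id", "image_id", "kind",
                        "onset", "offset", "duration")

  gt <- list(
    seed = cfg$seed,
    face_velocity_boost = cfg$face_velocity_boost,
    face_shortening = cfg$duration_model$face_shortening,
    sd_velocity_ref = sd_v,
    n_trials = Tn,
    n_saccades = nrow(sc),
    n_face_saccades = sum(sc$face),
    n_planted_corrective = sum(sc$corrective),
    random_effect_sds = as.list(re),
    saccade_log = tibble::tibble(
      subject_id = sprintf("s%03d", subj_idx[sc$ti]),
      trial_id = img_ids[img_idx[sc$ti]],
      onset = sc$onset, offset = sc$offset, amplitude = sc$amp,
      face_target = sc$face, object = sc$obj, corrective = sc$corrective))
  list(events = ev, ground_truth = gt, scenes = scenes)
}

#' Serialize generator ground truth as JSON
#'
#' @param ground_truth The `ground_truth` element of [generate_gaze()].
#' @param path Output path.
#' @export
write_ground_truth <- function(ground_truth, path) {
  gt <- ground_truth
  gt$saccade_log <- NULL
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Render event tables to 2 kHz gaze sample streams
#'
#' Fixations hold position with a small tremor; saccades follow a
#' straight-line trajectory with a trapezoidal velocity profile (1 ms
#' rise/fall ramps), which gives the sharp velocity onsets real saccades
#' show and keeps threshold-detected boundaries within about a sample of
#' the generating event boundaries; blinks hold position with `valid =
#' FALSE`. One stream per trial at `cfg$sample_hz`.
#'
#' @param events Event tibble (generator output or the
#'   [detect_events()] schema).
#' @param cfg A [synth_config()] (for the sampling rate).
#' @param tremor_sd Fixational tremor SD, dva per sample.
#' @return A samples tibble (`subject_id`, `trial_id`, `t`, `x`, `y`,
#'   `valid`).
#' @export
render_samples <- function(events, cfg, tremor_sd = 0.002) {
  dt <- 1000 / cfg$sample_hz
  keys <- paste(events$subject_id, events$trial_id, sep = "\r")
  parts <- split(seq_len(nrow(events)), factor(keys, levels = unique(keys)))
  out <- lapply(parts, function(idx) {
    tr <- events[idx, , drop = FALSE]
    tr <- tr[order(tr$onset), , drop = FALSE]
    t0 <- tr$onset[1]
    tmax <- max(tr$offset)
    t <- seq(t0, tmax - dt / 2, by = dt)
    ei <- findInterval(t, tr$onset)
    x <- numeric(length(t)); y <- numeric(length(t))
    valid <- rep(TRUE, length(t))
    for (j in seq_len(nrow(tr))) {
      sel <- which(ei == j & t < tr$offset[j])
      if (length(sel) == 0) next
      if (tr$kind[j] == "saccade") {
        prog <- trapezoid_progress(t[sel] - tr$onset[j],
                                   tr$offset[j] - tr$onset[j])
        x[sel] <- tr$x_start[j] + (tr$x_end[j] - tr$x_start[j]) * prog
        y[sel] <- tr$y_start[j] + (tr$y_end[j] - tr$y_start[j]) * prog
      } else {
        x[sel] <- tr$x_mean[j] + rnorm(length(sel), 0, tremor_sd)
        y[sel] <- tr$y_mean[j] + rnorm(length(sel), 0, tremor_sd)
        if (tr$kind[j] == "blink") valid[sel] <- FALSE
      }
    }
    tibble::tibble(subject_id = tr$subject_id[1], trial_id = tr$trial_id[1],
                   t = t, x = x, y = y, valid = valid)
  })
  dplyr::bind_rows(out)
}

# fraction of path covered at time s into a saccade of duration D with a
# trapezoidal speed profile (ramp r = 1 ms)
trapezoid_progress <- function(s, D, r = 1) {
  if (D <= 2 * r) return(pmin(pmax(s / D, 0), 1))
  # peak speed for unit path: vp * (D - r) = 1
  vp <- 1 / (D - r)
  p <- numeric(length(s))
  i1 <- s < r
  p[i1] <- vp * s[i1]^2 / (2 * r)
  i2 <- s >= r & s < (D - r)
  p[i2] <- vp * (r / 2 + (s[i2] - r))
  i3 <- s >= (D - r)
  p[i3] <- 1 - vp * (D - s[i3])^2 / (2 * r)
  pmin(pmax(p, 0), 1)
}
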