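# shared fixture builders; everything is generated in code

event_row <- function(kind, onset, offset, x0, y0, x1 = x0, y1 = y0,
                      pv = NA_real_, subject = "s1", trial = "t1",
                      image = "img1") {
  tibble::tibble(
    subject_id = subject, trial_id = trial, image_id = image,
    kind = kind, onset = onset, offset = offset, duration = offset - onset,
    x_start = x0, y_start = y0, x_end = x1, y_end = y1,
    x_mean = (x0 + x1) / 2, y_mean = (y0 + y1) / 2,
    amplitude = if (kind == "saccade") sqrt((x1 - x0)^2 + (y1 - y0)^2)
                else NA_real_,
    peak_velocity = if (kind == "saccade") pv else NA_real_,
    flags = "")
}

# 20 hand-built events in one trial, one designed rule violation each;
# expected flags are known by construction
make_cascade_fixture <- function() {
  ev <- dplyr::bind_rows(
    event_row("fixation", 0, 150, 5, 5),                  # 1 early_onset
    event_row("saccade", 150, 180, 5, 5, 9, 8, pv = 300), # 2 retained
    event_row("fixation", 180, 400, 9, 8),                # 3 retained
    event_row("saccade", 400, 430, 9, 8, 9.96, 8.72, pv = 120), # 4 corrective
    event_row("fixation", 430, 600, 9.96, 8.72),          # 5 retained
    event_row("saccade", 600, 640, 9.96, 8.72, 15, 12, pv = 400), # 6 retained
    event_row("fixation", 640, 730, 15, 12),              # 7 short_fixation
    event_row("saccade", 730, 760, 15, 12, 20, 15, pv = 350), # 8 retained
    event_row("fixation", 760, 1900, 20, 15),             # 9 over_duration
    event_row("saccade", 1900, 1930, 20, 15, 14, 10, pv = 1100), # 10 over_vel
    event_row("fixation", 1930, 2045, 14, 10),            # 11 retained
    event_row("blink", 2150, 2200, 14, 10),               # 12 blink (clean)
    event_row("saccade", 2230, 2260, 14, 10, 18, 13, pv = 300), # 13 blink_adj
    event_row("fixation", 2310, 2490, 18, 13),            # 14 retained
    event_row("fixation", 2500, 2650, 31, 5),             # 15 off_image
    event_row("saccade", 2650, 2680, 18, 13, 25, 18, pv = 450), # 16 retained
    event_row("fixation", 2680, 2800, 25, 18),            # 17 retained
    event_row("saccade", 2800, 2830, 25, 18, 28, 20.2, pv = 280), # 18 retained
    event_row("fixation", 2830, 2950, 28, 20.2),          # 19 retained
    event_row("saccade", 2950, 2980, 28, 20.2, 30.5, 21, pv = 320)) # 20 off_im
  expected <- c("early_onset", "", "", "corrective", "", "",
                "short_fixation", "", "over_duration", "over_velocity",
                "", "", "blink_adjacent", "", "off_image",
                "", "", "", "", "off_image")
  list(events = ev, expected = expected)
}

# small annotated scene: two rectangular objects on a coarse grid
make_tiny_scene <- function(width_px = 120, height_px = 90,
                            image_id = "img1") {
  geom <- screen_geometry(width_px, height_px)
  lm <- matrix(0L, height_px, width_px)
  lm[20:40, 10:35] <- 1L   # inanimate object
  lm[50:75, 70:100] <- 2L  # face
  scene_annotation(image_id, geom,
                   labels = list("inanimate_object",
                                 c("inner_face", "head", "person")),
                   label_mat = lm)
}

# brute-force oracles: full-grid pixel scans, independent of the
# package's windowed disc computation
brute_disc_index <- function(point, geom, radius) {
  W <- geom$width_px; H <- geom$height_px
  ix <- rep(0:(W - 1), each = H)
  iy <- rep(0:(H - 1), times = W)
  cx <- point[1] * geom$px_per_dva_x
  cy <- point[2] * geom$px_per_dva_y
  if (radius == 0) {
    px <- min(max(floor(cx), 0), W - 1)
    py <- min(max(floor(cy), 0), H - 1)
    return(which(ix == px & iy == py))
  }
  rx <- radius * geom$px_per_dva_x
  ry <- radius * geom$px_per_dva_y
  which(((ix + 0.5 - cx) / rx)^2 + ((iy + 0.5 - cy) / ry)^2 <= 1)
}

brute_labels_at <- function(point, annot, radius) {
  idx <- brute_disc_index(point, annot$geom, radius)
  vals <- if (!is.null(annot$label_mat)) annot$label_mat[idx] else {
    stop("brute oracle needs a label matrix")
  }
  sort(unique(vals[vals > 0]))
}

brute_salience_at <- function(point, smap, radius) {
  idx <- brute_disc_index(point, smap$geom, radius)
  sum(smap$values[idx])
}

# direct stepwise enumeration of the Holm rejection rule
holm_oracle <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  reject <- logical(m)
  for (k in seq_len(m)) {
    if (p[ord[k]] < alpha / (m - k + 1)) reject[ord[k]] <- TRUE else break
  }
  reject
}

# exhaustive enumeration of the AIC-difference selection rule
aic_oracle <- function(aics, npar, converged, delta_max = 2) {
  delta <- aics - min(aics[converged])
  elig <- which(converged & delta < delta_max)
  elig[which.min(npar[elig])]
}

fake_fit <- function(aic, n_par, converged = TRUE) {
  list(aic = aic, n_par = n_par, converged = converged)
}

skewness <- function(x) mean((x - mean(x))^3) / sd(x)^3
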