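test_that("generation is deterministic under a fixed seed", {
  cfg <- synth_config(n_subjects = 2, n_images = 5, seed = 123)
  a <- generate_gaze(cfg)
  b <- generate_gaze(cfg)
  expect_identical(a$events, b$events)
  expect_identical(a$scenes$annotations[["img0001"]]$label_mat,
                   b$scenes$annotations[["img0001"]]$label_mat)
  # a different seed changes the data
  cfg2 <- synth_config(n_subjects = 2, n_images = 5, seed = 124)
  expect_false(identical(generate_gaze(cfg2)$events, a$events))
})

test_that("scene layout follows the configured label probabilities", {
  cfg <- synth_config(n_subjects = 1, n_images = 30, seed = 3,
                      scene_layout = list(n_objects = 6, face_prob = 0,
                                          body_prob = 0.1, animal_prob = 0,
                                          size_range = c(1, 4)))
  scenes <- generate_scenes(cfg)
  has_face <- vapply(scenes$annotations, function(a)
    any(vapply(a$objects$labels, function(l) "inner_face" %in% l,
               logical(1))), logical(1))
  expect_false(any(has_face))
  expect_true(all(vapply(scenes$annotations,
                         function(a) nrow(a$objects), integer(1)) == 6))

  cfg1 <- synth_config(n_subjects = 1, n_images = 5, seed = 4,
                       scene_layout = list(n_objects = 1, face_prob = 0.5,
                                           body_prob = 0, animal_prob = 0,
                                           size_range = c(1, 3)))
  n_obj <- vapply(generate_scenes(cfg1)$annotations,
                  function(a) nrow(a$objects), integer(1))
  expect_true(all(n_obj == 1))
})

test_that("empirical face frequency approximates the configured probability", {
  p <- 0.12
  cfg <- synth_config(n_subjects = 1, n_images = 150, seed = 5)
  scenes <- generate_scenes(cfg)
  n_face <- sum(vapply(scenes$annotations, function(a)
    sum(a$category == "face"), numeric(1)))
  n_tot <- 150 * cfg$scene_layout$n_objects
  phat <- n_face / n_tot
  tol <- 3 * sqrt(p * (1 - p) / n_tot)
  expect_lt(abs(phat - p), tol)
})

test_that("peak velocity follows an increasing, saturating main sequence", {
  cfg <- synth_config(n_subjects = 5, n_images = 40, seed = 6)
  sim <- generate_gaze(cfg)
  sac <- sim$events[sim$events$kind == "saccade", ]
  sac <- sac[sac$peak_velocity < 1000, ] # planted outliers aside
  expect_gt(cor(sac$peak_velocity, sac$amplitude), 0.8)
  bins <- cut(sac$amplitude, seq(0, 24, 2))
  m <- tapply(sac$peak_velocity, bins, mean)
  m <- m[!is.na(m)]
  expect_true(all(diff(m) > 0))         # increasing
  k <- length(m) %/% 2
  slope_lo <- (m[k] - m[1]) / (k - 1)
  slope_hi <- (m[length(m)] - m[k]) / (length(m) - k)
  expect_gt(slope_lo, slope_hi)         # concave (saturating)
})

test_that("generated fixation durations are right-skewed", {
  cfg <- synth_config(n_subjects = 3, n_images = 30, seed = 7)
  sim <- generate_gaze(cfg)
  fix <- sim$events[sim$events$kind == "fixation", ]
  expect_gt(skewness(fix$duration), 0)
})

test_that("saccade directions persist with the configured tendency", {
  cfg_hi <- synth_config(n_subjects = 3, n_images = 30, seed = 8,
                         direction_persistence = 0.9)
  cfg_lo <- synth_config(n_subjects = 3, n_images = 30, seed = 8,
                         direction_persistence = 0)
  frac_same <- function(cfg) {
    sim <- generate_gaze(cfg)
    ev <- apply_cascade(sim$events, geom = sim$scenes$geom)
    ser <- build_series(ev, sim$scenes$annotations)
    mean(ser$angle < 60)
  }
  expect_gt(frac_same(cfg_hi), frac_same(cfg_lo) + 0.05)
})

test_that("rendered streams re-parse into the planted events", {
  cfg <- synth_config(n_subjects = 1, n_images = 25, seed = 9)
  sim <- generate_gaze(cfg)
  set.seed(10)
  smp <- render_samples(sim$events, cfg)
  det <- detect_events(smp)
  log <- sim$ground_truth$saccade_log
  matched <- 0; errs <- c()
  for (tr in unique(log$trial_id)) {
    pl <- log[log$trial_id == tr, ]
    dt <- det[det$trial_id == tr & det$kind == "saccade", ]
    for (i in seq_len(nrow(pl))) {
      d <- abs(dt$onset - pl$onset[i])
      if (length(d) > 0 && min(d) <= 2.5) {
        j <- which.min(d)
        matched <- matched + 1
        errs <- c(errs, abs(dt$onset[j] - pl$onset[i]),
                  abs(dt$offset[j] - pl$offset[i]))
      }
    }
  }
  expect_gt(matched / nrow(log), 0.95)
  # boundary errors in samples (0.5 ms each)
  expect_gt(mean(errs <= 1.0), 0.95)
})

test_that("planted artifacts exercise every cascade rule", {
  cfg <- synth_config(n_subjects = 5, n_images = 50, seed = 11)
  sim <- generate_gaze(cfg)
  ev <- apply_cascade(sim$events, geom = sim$scenes$geom)
  rep <- exclusion_report(ev)
  frac <- setNames(rep$fraction, rep$rule_id)
  expect_gt(frac["early_onset"], 0)
  expect_gt(frac["short_fixation"], 0)
  expect_gt(frac["blink_adjacent"], 0)
  expect_gt(frac["corrective"], 0)
  expect_gt(frac["over_velocity"], 0)
  expect_gt(frac["over_duration"], 0)
})

test_that("configuration validation rejects impossible settings", {
  expect_error(synth_config(direction_persistence = 1.4), "\\[0, 1\\]")
  expect_error(synth_config(n_subjects = 0), "positive")
  expect_error(synth_config(duration_model = list(
    meanlog = 5.3, sdlog = -1, face_shortening = 0, onset_slope = 0,
    angle_slope = 0, incoming_amplitude_slope = 0)), "positive")
})

test_that("ground truth serializes with the planted effects", {
  cfg <- synth_config(n_subjects = 1, n_images = 3, seed = 13)
  sim <- generate_gaze(cfg)
  f <- tempfile(fileext = ".json")
  write_ground_truth(sim$ground_truth, f)
  gt <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(gt$face_velocity_boost, 0.07)
  expect_equal(gt$face_shortening, -0.08)
  expect_equal(gt$seed, 13)
})
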