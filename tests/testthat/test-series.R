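# a minimal trial on the tiny two-object scene: saccade onto the
# inanimate object, fixation there, saccade onto the face, fixation there
make_minimal_trial <- function(annot) {
  g <- annot$geom
  p_inan <- c(22 / g$px_per_dva_x, 30 / g$px_per_dva_y)  # inside object 1
  p_tgt <- c(85 / g$px_per_dva_x, 62 / g$px_per_dva_y)   # inside object 2
  dplyr::bind_rows(
    event_row("saccade", 200, 240, 2, 2, p_inan[1], p_inan[2], pv = 250),
    event_row("fixation", 240, 500, p_inan[1], p_inan[2]),
    event_row("saccade", 500, 540, p_inan[1], p_inan[2],
              p_tgt[1], p_tgt[2], pv = 320),
    event_row("fixation", 540, 900, p_tgt[1], p_tgt[2]))
}

test_that("a minimal valid chain produces exactly one face-directed series", {
  annot <- make_tiny_scene()
  ev <- make_minimal_trial(annot)
  ser <- build_series(ev, annot)
  expect_equal(nrow(ser), 1)
  expect_equal(ser$target_category, "face")
  expect_equal(ser$visual_object_id, 2L)
  expect_equal(ser$intermediate_duration, 260)
  expect_equal(ser$onset_time, 500)
  expect_equal(ser$peak_velocity, 320)
  expect_equal(ser$target_size, annot$objects$area_fraction[2])
  expect_equal(ser$incoming_amplitude, ev$amplitude[1])
  expect_equal(ser$target_amplitude, ev$amplitude[3])
})

test_that("the full predictor record matches hand computation on a fixture", {
  annot <- make_tiny_scene()
  ev <- make_minimal_trial(annot)
  uni <- saliency_map("img1", matrix(2, annot$geom$height_px,
                                     annot$geom$width_px), annot$geom)
  ser <- featurize(build_series(ev, annot), uni)
  # angle between the two saccade direction vectors, by hand
  d1 <- c(ev$x_end[1] - ev$x_start[1], ev$y_end[1] - ev$y_start[1])
  d2 <- c(ev$x_end[3] - ev$x_start[3], ev$y_end[3] - ev$y_start[3])
  ang <- acos(sum(d1 * d2) / sqrt(sum(d1^2) * sum(d2^2))) * 180 / pi
  expect_equal(ser$angle, ang, tolerance = 1e-10)
  # uniform map of value 2: disc sum = 2 x disc pixel count
  n_px <- length(brute_disc_index(c(ser$target_x, ser$target_y),
                                  annot$geom, 0.5))
  expect_equal(ser$gbvs_target, 2 * n_px)
  # without maps the salience fields are missing but the record is kept
  ser0 <- featurize(build_series(ev, annot), NULL)
  expect_equal(nrow(ser0), 1)
  expect_true(is.na(ser0$gbvs_target))
})

test_that("an intermediate fixation on a face disqualifies the series", {
  annot <- make_tiny_scene()
  g <- annot$geom
  p_face <- c(85 / g$px_per_dva_x, 62 / g$px_per_dva_y)
  p_inan <- c(22 / g$px_per_dva_x, 30 / g$px_per_dva_y)
  ev <- dplyr::bind_rows(
    event_row("saccade", 200, 240, 2, 2, p_face[1], p_face[2], pv = 250),
    event_row("fixation", 240, 500, p_face[1], p_face[2]),
    event_row("saccade", 500, 540, p_face[1], p_face[2],
              p_inan[1], p_inan[2], pv = 320),
    event_row("fixation", 540, 900, p_inan[1], p_inan[2]))
  expect_equal(nrow(build_series(ev, annot)), 0)
})

test_that("target saccades must start and land on different visual objects", {
  annot <- make_tiny_scene()
  g <- annot$geom
  p1 <- c(15 / g$px_per_dva_x, 25 / g$px_per_dva_y) # inside object 1
  p2 <- c(30 / g$px_per_dva_x, 35 / g$px_per_dva_y) # also inside object 1
  ev <- dplyr::bind_rows(
    event_row("saccade", 200, 240, 2, 2, p1[1], p1[2], pv = 250),
    event_row("fixation", 240, 500, p1[1], p1[2]),
    event_row("saccade", 500, 540, p1[1], p1[2], p2[1], p2[2], pv = 320),
    event_row("fixation", 540, 900, p2[1], p2[2]))
  expect_equal(nrow(build_series(ev, annot)), 0)
})

test_that("excluded events break chains instead of being bridged", {
  annot <- make_tiny_scene()
  ev <- make_minimal_trial(annot)
  ev$flags[2] <- "short_fixation" # the intermediate fixation is excluded
  expect_equal(nrow(build_series(ev, annot)), 0)
})

test_that("dropping the animal exclusion never decreases the series count", {
  geom <- screen_geometry(120, 90)
  lm <- matrix(0L, 90, 120)
  lm[20:40, 10:35] <- 1L
  lm[50:75, 70:100] <- 2L
  annot <- scene_annotation("img1", geom,
                            labels = list("inanimate_object", "animal"),
                            label_mat = lm)
  ev <- make_minimal_trial(annot) # target point lands on the animal
  with_animals <- build_series(ev, annot, exclude_animals = FALSE)
  without <- build_series(ev, annot, exclude_animals = TRUE)
  expect_gte(nrow(with_animals), nrow(without))
  expect_equal(nrow(without), 0)
  expect_equal(with_animals$target_category, "animal")
})

test_that("longer chains yield multiple series sharing events", {
  annot <- make_tiny_scene()
  g <- annot$geom
  p1 <- c(22 / g$px_per_dva_x, 30 / g$px_per_dva_y) # object 1
  p2 <- c(85 / g$px_per_dva_x, 62 / g$px_per_dva_y) # object 2 (face)
  p3 <- c(15 / g$px_per_dva_x, 25 / g$px_per_dva_y) # object 1 again
  ev <- dplyr::bind_rows(
    event_row("saccade", 200, 240, 2, 2, p1[1], p1[2], pv = 250),
    event_row("fixation", 240, 500, p1[1], p1[2]),
    event_row("saccade", 500, 540, p1[1], p1[2], p2[1], p2[2], pv = 320),
    event_row("fixation", 540, 800, p2[1], p2[2]),
    event_row("saccade", 800, 840, p2[1], p2[2], p3[1], p3[2], pv = 300),
    event_row("fixation", 840, 1100, p3[1], p3[2]))
  ser <- build_series(ev, annot)
  # only the first quadruple qualifies (the second has a face
  # intermediate), so exactly one series from the shared chain
  expect_equal(nrow(ser), 1)
  expect_equal(ser$target_category, "face")
})

test_that("missing annotations skip the trial with a warning", {
  annot <- make_tiny_scene()
  ev <- make_minimal_trial(annot)
  ev$image_id <- "unknown_image"
  expect_warning(ser <- build_series(ev, list(img1 = annot)),
                 "no annotation")
  expect_equal(nrow(ser), 0)
})

test_that("series construction is reproducible bit-exact", {
  cfg <- synth_config(n_subjects = 2, n_images = 6, seed = 12)
  sim <- generate_gaze(cfg)
  ev <- apply_cascade(sim$events, geom = sim$scenes$geom)
  s1 <- build_series(ev, sim$scenes$annotations)
  s2 <- build_series(ev, sim$scenes$annotations)
  expect_identical(s1, s2)
})
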