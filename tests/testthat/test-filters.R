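geom_std <- screen_geometry(800, 600)

test_that("onset and duration rules use strict 100 ms cutoffs", {
  ev <- dplyr::bind_rows(
    event_row("fixation", 99, 300, 1, 1),
    event_row("fixation", 100, 300, 2, 2),
    event_row("fixation", 0, 300, 3, 3),
    event_row("saccade", 500, 550, 1, 1, 4, 4, pv = 200),
    event_row("fixation", 600, 699, 4, 4),   # 99 ms
    event_row("fixation", 700, 800, 4, 4))   # 100 ms exactly
  out <- flag_early_onset(ev)
  expect_equal(flag_hits(out$flags, "early_onset"),
               c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
  out <- flag_short_fixations(ev)
  expect_equal(flag_hits(out$flags, "short_fixation"),
               c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE))
  # saccades are untouched by the fixation-duration rule
  short_sac <- event_row("saccade", 200, 250, 0, 0, 1, 1, pv = 100)
  expect_equal(flag_short_fixations(short_sac)$flags, "")
})

test_that("blink adjacency flags events intersecting the 100 ms guard window", {
  blink <- event_row("blink", 1000, 1100, 5, 5)
  near <- event_row("saccade", 900, 950, 1, 1, 3, 3, pv = 150)  # ends 50 ms before
  far <- event_row("saccade", 700, 750, 1, 1, 3, 3, pv = 150)   # ends 250 ms before
  after <- event_row("fixation", 1150, 1350, 3, 3)              # starts 50 ms after
  ev <- dplyr::bind_rows(near, far, after, blink)
  out <- flag_blink_adjacent(ev)
  expect_equal(flag_hits(out$flags, "blink_adjacent"),
               c(TRUE, FALSE, TRUE, FALSE))
  # no blinks: nothing flagged
  expect_equal(flag_blink_adjacent(dplyr::bind_rows(near, far))$flags,
               c("", ""))
})

test_that("corrective saccades need < 30% amplitude and a near-collinear angle", {
  prev <- event_row("saccade", 0, 40, 0, 0, 10, 0, pv = 400) # 10 dva, rightward
  mk <- function(amp, angle_deg) {
    event_row("saccade", 200, 230, 10, 0,
              10 + amp * cos(angle_deg * pi / 180),
              amp * sin(angle_deg * pi / 180), pv = 100)
  }
  expect_true(is_corrective(prev, mk(2, 10)))    # small, same-directed
  expect_false(is_corrective(prev, mk(4, 10)))   # 4 >= 3 = 30% of 10
  expect_false(is_corrective(prev, mk(2, 90)))   # angle outside both bands
  expect_true(is_corrective(prev, mk(2, 170)))   # small, opposite-directed
  expect_false(is_corrective(prev, mk(2, 25)))   # outside the 20 deg band
  # exact 30% amplitude boundary (collinear, so both values are exact):
  # strict inequality retains it
  boundary <- event_row("saccade", 200, 230, 10, 0, 13, 0, pv = 100)
  expect_false(is_corrective(prev, boundary))
  zero <- event_row("saccade", 0, 40, 0, 0, 0, 0, pv = 0)
  expect_warning(res <- is_corrective(zero, mk(1, 0)), "zero-amplitude")
  expect_false(res)
})

test_that("corrective flagging skips flagged predecessors", {
  # big saccade (flagged early), then a small one: the small saccade must
  # be compared against the nearest *retained* predecessor, not the
  # flagged one
  ev <- dplyr::bind_rows(
    event_row("saccade", 50, 90, 0, 0, 10, 0, pv = 400),   # early_onset
    event_row("fixation", 90, 250, 10, 0),
    event_row("saccade", 250, 280, 10, 0, 12, 0, pv = 200), # retained, 2 dva
    event_row("fixation", 280, 450, 12, 0),
    event_row("saccade", 450, 480, 12, 0, 13.8, 0, pv = 150)) # 1.8 dva
  out <- flag_corrective(flag_early_onset(ev))
  # 1.8 dva is 90% of the retained 2-dva predecessor: not corrective,
  # although it is 18% of the flagged 10-dva saccade
  expect_false(flag_hits(out$flags, "corrective")[5])
})

test_that("over-limit rules use strict thresholds", {
  ev <- dplyr::bind_rows(
    event_row("fixation", 100, 1101, 1, 1),                    # 1001 ms
    event_row("fixation", 100, 1100, 2, 2),                    # 1000 ms
    event_row("saccade", 100, 150, 0, 0, 5, 5, pv = 1000),     # exactly 1000
    event_row("saccade", 100, 150, 0, 0, 5, 5, pv = 1200))
  out <- flag_over_limits(ev)
  expect_equal(flag_hits(out$flags, "over_duration"),
               c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(flag_hits(out$flags, "over_velocity"),
               c(FALSE, FALSE, FALSE, TRUE))
})

test_that("off-image rule keeps the closed image boundary", {
  ev <- dplyr::bind_rows(
    event_row("fixation", 100, 300, -1, 5),
    event_row("fixation", 100, 300, 29.7, 22.3),  # exact corner retained
    event_row("fixation", 100, 300, 0, 0),
    event_row("saccade", 100, 150, 5, 5, 30, 10, pv = 300))
  out <- flag_off_image(ev, geom_std)
  expect_equal(flag_hits(out$flags, "off_image"),
               c(TRUE, FALSE, FALSE, TRUE))
})

test_that("the cascade flags the designed fixture exactly and is idempotent", {
  fx <- make_cascade_fixture()
  out <- apply_cascade(fx$events, geom = geom_std)
  expect_identical(out$flags, fx$expected)
  expect_identical(apply_cascade(out, geom = geom_std)$flags, fx$expected)
})

test_that("an all-clean table reports zero exclusion fractions", {
  ev <- dplyr::bind_rows(
    event_row("fixation", 200, 400, 5, 5),
    event_row("saccade", 400, 430, 5, 5, 10, 8, pv = 300),
    event_row("fixation", 430, 700, 10, 8))
  rep <- exclusion_report(apply_cascade(ev, geom = geom_std))
  expect_true(all(rep$fraction == 0))
  expect_true(all(rep$n_flagged == 0))
})

test_that("the exclusion report accounts for every event", {
  fx <- make_cascade_fixture()
  out <- apply_cascade(fx$events, geom = geom_std)
  rep <- exclusion_report(out)
  n_any <- rep$n_flagged[rep$rule_id == "any"]
  expect_equal(n_any + sum(out$flags == ""), nrow(out))
  expect_true(all(rep$fraction >= 0 & rep$fraction <= 1))
  # per-rule designed counts: one violation per rule, two off-image
  counts <- setNames(rep$n_flagged, rep$rule_id)
  expect_equal(unname(counts[c("early_onset", "short_fixation",
                               "blink_adjacent", "corrective",
                               "over_duration", "over_velocity",
                               "off_image")]),
               c(1, 1, 1, 1, 1, 1, 2))
})

test_that("exclusion reports round-trip through TSV and JSON", {
  fx <- make_cascade_fixture()
  rep <- exclusion_report(apply_cascade(fx$events, geom = geom_std))
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  write_exclusion_report(rep, tsv, js)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(back$n_flagged, rep$n_flagged)
  expect_equal(jsonlite::read_json(js, simplifyVector = TRUE)$rule_id,
               rep$rule_id)
})
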