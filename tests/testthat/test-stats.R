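# small featurized series table with controllable structure
make_series_table <- function(n = 400, face_frac = 0.3, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    subject_id = sample(sprintf("s%02d", 1:8), n, replace = TRUE),
    trial_id = sample(sprintf("t%02d", 1:20), n, replace = TRUE),
    image_id = sample(sprintf("i%02d", 1:20), n, replace = TRUE),
    visual_object_id = sample(1:5, n, replace = TRUE),
    target_category = sample(c("face", "inanimate"), n, replace = TRUE,
                             prob = c(face_frac, 1 - face_frac)),
    target_amplitude = runif(n, 1, 14),
    incoming_amplitude = runif(n, 1, 14),
    target_size = runif(n, 0.5, 40),
    onset_time = runif(n, 100, 2700),
    angle = runif(n, 0, 180),
    gbvs_intermediate = runif(n, 10, 390),
    gbvs_target = runif(n, 10, 390),
    peak_velocity = rnorm(n, 350, 80),
    intermediate_duration = rlnorm(n, 5.3, 0.45))
}

test_that("standardized columns have mean 0 and unit variance", {
  ser <- make_series_table()
  tab <- standardize(ser, "peak_velocity")
  for (p in attr(tab, "predictors")) {
    expect_lt(abs(mean(tab[[p]])), 1e-9)
    expect_lt(abs(sd(tab[[p]]) - 1), 1e-9)
  }
  expect_lt(abs(mean(tab$y)), 1e-9)
  expect_lt(abs(sd(tab$y) - 1), 1e-9)
  expect_true(all(tab$category %in% c(0, 1)))
})

test_that("a zero-variance column raises an error naming the column", {
  ser <- make_series_table()
  ser$target_size <- 5
  expect_error(standardize(ser, "peak_velocity"), "target_size")
})

test_that("log-then-z of a log-normal response removes right-skewness", {
  ser <- make_series_table(n = 5000, seed = 3)
  expect_gt(skewness(ser$intermediate_duration), 0.5)
  tab <- standardize(ser, "intermediate_duration", log_duration = TRUE)
  expect_lt(abs(skewness(tab$y)), 0.15)
  # z-scoring alone does not remove skewness
  raw <- standardize(ser, "intermediate_duration", log_duration = FALSE)
  expect_gt(skewness(raw$y), 0.5)
})

test_that("near-noiseless planted fixed effects are recovered to 6 decimals", {
  set.seed(11)
  n <- 600
  tab <- tibble::tibble(
    category = rbinom(n, 1, 0.3),
    target_amplitude = rnorm(n), onset_time = rnorm(n),
    subject = factor(sample(1:6, n, TRUE)),
    image = factor(sample(1:10, n, TRUE)),
    object = factor(sample(1:15, n, TRUE)))
  b <- c(category = 0.07, target_amplitude = 0.74, onset_time = 0.02)
  tab$y <- 0.3 + b["category"] * tab$category +
    b["target_amplitude"] * tab$target_amplitude +
    b["onset_time"] * tab$onset_time + rnorm(n, 0, 1e-8)
  attr(tab, "predictors") <- c("target_amplitude", "onset_time")
  fit <- fit_lmm(tab, random = c(subject = "intercept"))
  co <- tidy(fit)
  for (term in names(b)) {
    expect_equal(co$estimate[co$term == term], unname(b[term]),
                 tolerance = 1e-6)
  }
})

test_that("fit_lmm recovers a planted effect with crossed random effects", {
  set.seed(21)
  n <- 4000
  subj <- factor(sample(1:20, n, TRUE))
  img <- factor(sample(1:40, n, TRUE))
  u_s <- rnorm(20, 0, 0.3); u_i <- rnorm(40, 0, 0.2)
  tab <- tibble::tibble(
    category = rbinom(n, 1, 0.3),
    target_amplitude = rnorm(n),
    subject = subj, image = img,
    object = factor(sample(1:80, n, TRUE)))
  tab$y <- 0.25 * tab$category + 0.7 * tab$target_amplitude +
    u_s[as.integer(subj)] + u_i[as.integer(img)] + rnorm(n, 0, 1)
  attr(tab, "predictors") <- "target_amplitude"
  fit <- fit_lmm(tab, random = c(subject = "intercept", image = "intercept"))
  co <- tidy(fit)
  est <- co$estimate[co$term == "category"]
  se <- co$std.error[co$term == "category"]
  expect_lt(abs(est - 0.25), 2.5 * se)
  expect_true(fit$converged)
  expect_equal(co$df[1], fit$n - nrow(co))
  g <- glance(fit)
  expect_true(is.finite(g$AIC))
})

test_that("the AIC difference rule returns the simplest model on par", {
  # delta = 1.5 < 2: the simpler second model wins
  pick <- aic_delta_select(list(fake_fit(100.0, 10), fake_fit(101.5, 8)))
  expect_equal(pick$aic, 101.5)
  # delta = 3 >= 2: the better first model wins
  pick <- aic_delta_select(list(fake_fit(100.0, 10), fake_fit(103.0, 8)))
  expect_equal(pick$aic, 100.0)
  # identical AICs: fewest parameters
  pick <- aic_delta_select(list(fake_fit(100.0, 10), fake_fit(100.0, 8)))
  expect_equal(pick$n_par, 8)
  # non-converged candidates are skipped entirely
  pick <- aic_delta_select(list(fake_fit(90, 4, converged = FALSE),
                                fake_fit(100, 10)))
  expect_equal(pick$aic, 100)
  expect_error(aic_delta_select(list(fake_fit(90, 4, FALSE))),
               "no converged")
})

test_that("aic_delta_select agrees with exhaustive enumeration", {
  set.seed(17)
  for (i in 1:50) {
    k <- sample(2:8, 1)
    aics <- round(runif(k, 100, 110), 2)
    npar <- sample(3:12, k, replace = TRUE)
    conv <- runif(k) > 0.1
    if (!any(conv)) conv[1] <- TRUE
    fits <- Map(fake_fit, aics, npar, conv)
    pick <- aic_delta_select(fits)
    oracle <- aic_oracle(aics, npar, conv)
    expect_equal(pick$aic, aics[oracle])
    expect_equal(pick$n_par, npar[oracle])
  }
})

test_that("binned ANOVA detects planted structure and flat interactions", {
  set.seed(31)
  ser <- make_series_table(n = 6000, seed = 31)
  # additive category shift, no interaction
  ser$peak_velocity <- 300 + 20 * (ser$target_category == "face") +
    0.5 * ser$angle + rnorm(nrow(ser), 0, 10)
  res <- binned_anova(ser, "angle", response = "peak_velocity")
  tab <- tidy(res)
  expect_gt(tab$statistic[tab$term == "category"], 100)
  expect_gt(tab$statistic[tab$term == "bin"], 10)
  expect_gt(tab$p.value[tab$term == "category:bin"], 0.001)
  expect_lt(tab$eta_sq[tab$term == "category:bin"], 0.01)
  expect_true(all(tab$eta_sq >= 0 & tab$eta_sq <= 1, na.rm = TRUE))
  expect_equal(sum(tab$eta_sq), 1)
  # equal cell means: interaction F near 0 on a balanced exact design
  bal <- tidyr::expand_grid(target_category = c("face", "inanimate"),
                            angle = seq(6, 174, by = 12), rep = 1:3)
  bal$peak_velocity <- 10 + (bal$target_category == "face") * 5 + bal$angle
  bal$subject_id <- "s1"
  res2 <- binned_anova(bal, "angle", response = "peak_velocity")
  eta_int <- tidy(res2)$eta_sq[tidy(res2)$term == "category:bin"]
  expect_lt(eta_int, 1e-12) # no interaction variance in an additive design
})

test_that("interaction p-values are uniform under label shuffling", {
  set.seed(41)
  ser <- make_series_table(n = 1200, seed = 41)
  ps <- replicate(60, {
    ser$target_category <- sample(ser$target_category)
    res <- binned_anova(ser, "angle", response = "peak_velocity",
                        bins = seq(0, 180, 36))
    tidy(res)$p.value[3]
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("binned ANOVA validates its inputs", {
  ser <- make_series_table(n = 50)
  ser$angle <- 5 # everything in one bin
  expect_error(binned_anova(ser, "angle", response = "peak_velocity"),
               "fewer than 2 bins")
  ser2 <- make_series_table(n = 2000, seed = 2)
  ser2$angle[ser2$angle > 150] <- 75 # empty top bins
  expect_warning(binned_anova(ser2, "angle", response = "peak_velocity"),
                 "empty cell")
})

test_that("Holm post hocs match the stepwise enumeration oracle", {
  set.seed(51)
  for (i in 1:10) {
    ser <- make_series_table(n = 2500, seed = 100 + i)
    # plant a difference in some bins only
    shift <- 30 * (ser$angle < 60) * (ser$target_category == "face")
    ser$peak_velocity <- ser$peak_velocity + shift
    ph <- suppressWarnings(
      holm_posthoc(ser, "angle", bins = seq(0, 180, 30),
                   response = "peak_velocity"))
    expect_equal(ph$significant, holm_oracle(ph$p.value, 0.05))
    # Holm rejections contain Bonferroni's and are within unadjusted ones
    bonf <- ph$p.value < 0.05 / nrow(ph)
    expect_true(all(bonf <= ph$significant))
    expect_true(all(ph$significant <= (ph$p.value < 0.05)))
  }
})

test_that("a single bin reduces Holm to a plain paired t-test", {
  ser <- make_series_table(n = 800, seed = 61)
  ph <- suppressWarnings(
    holm_posthoc(ser, "angle", bins = c(0, 180),
                 response = "peak_velocity"))
  expect_equal(nrow(ph), 1)
  expect_equal(ph$p.holm, ph$p.value)
  # cross-check the paired t statistic against a direct computation
  sm <- ser |>
    dplyr::group_by(.data$subject_id, .data$target_category) |>
    dplyr::summarise(m = mean(.data$peak_velocity), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "target_category", values_from = "m")
  tt <- t.test(sm$face - sm$inanimate)
  expect_equal(ph$statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(ph$p.value, tt$p.value, tolerance = 1e-12)
})

test_that("bins without enough pairs are dropped with a warning", {
  ser <- make_series_table(n = 60, seed = 71)
  ser$angle <- c(rep(10, 55), rep(170, 5))
  ser$target_category[ser$angle > 90] <- "face" # no pairs in the top bin
  expect_warning(ph <- holm_posthoc(ser, "angle", bins = c(0, 90, 180),
                                    response = "peak_velocity"),
                 "fewer than")
  expect_equal(nrow(ph), 1)
})
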