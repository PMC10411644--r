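#' Pipeline configuration
#'
#' Bundles every constant of the analysis with the study defaults: the
#' 100 ms onset and fixation-duration cutoffs, the 30% / 20 deg / 160 deg
#' corrective-saccade rule, the 1,000 ms and 1,000 deg/s limits, the
#' 0.5 dva foveation radius, family-wise alpha 0.05 and the AIC-difference
#' threshold 2. Any constant can be overridden for sensitivity analyses.
#' Inputs may be given as file paths (TSV schemas, annotation directories)
#' or as in-memory objects (`events`, `annotations`, `saliency`).
#'
#' @param events Event tibble, or path to an event TSV.
#' @param samples Samples tibble or path (used when `events` is `NULL`).
#' @param annotations Named list of [scene_annotation()], or a directory
#'   containing `<image>_mask.txt` / `<image>_labels.tsv` pairs.
#' @param saliency Named list of [saliency_map()], a directory of
#'   `<image>_saliency.txt` files, or `NULL`.
#' @param geom A [screen_geometry()].
#' @param radius Foveation radius, dva.
#' @param contrasts Category contrasts to fit against inanimate targets.
#' @param responses Response variables to model.
#' @param select_models Run the AIC-difference model sweep (random
#'   structures and leave-one-out fixed effects) instead of the single
#'   primary specification.
#' @param anova_controls Control predictors for the binned two-way ANOVAs.
#' @param alpha Family-wise error rate for post hoc tests.
#' @param delta_max AIC-difference threshold.
#' @param out_dir Output directory (`NULL` = return results only).
#' @param seed Seed for any stochastic step.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(events = NULL, samples = NULL,
                            annotations = NULL, saliency = NULL,
                            geom = screen_geometry(800, 600),
                            radius = 0.5,
                            contrasts = c("face", "body"),
                            responses = c("peak_velocity",
                                          "intermediate_duration"),
                            select_models = FALSE,
                            anova_controls = c("angle", "target_amplitude",
                                               "onset_time", "target_size",
                                               "gbvs_intermediate",
                                               "gbvs_target",
                                               "incoming_amplitude"),
                            alpha = 0.05, delta_max = 2,
                            out_dir = NULL, seed = 1L) {
  structure(
    list(events = events, samples = samples, annotations = annotations,
         saliency = saliency, geom = geom, radius = radius,
         contrasts = contrasts, responses = responses,
         select_models = select_models, anova_controls = anova_controls,
         alpha = alpha, delta_max = delta_max, out_dir = out_dir,
         seed = as.integer(seed)),
    class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; `geom`
#' is given as `geometry: {width_px, height_px, width_dva, height_dva}`.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  g <- y$geometry
  geom <- if (is.null(g)) screen_geometry(800, 600) else
    screen_geometry(g$width_px, g$height_px,
                    g$width_dva %||% 29.7, g$height_dva %||% 22.3)
  args <- y[setdiff(names(y), "geometry")]
  args$geom <- geom
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_annotation_dir <- function(dir, geom) {
  masks <- list.files(dir, pattern = "_mask\\.txt$", full.names = TRUE)
  out <- list()
  for (mf in masks) {
    img <- sub("_mask\\.txt$", "", basename(mf))
    lf <- file.path(dir, paste0(img, "_labels.tsv"))
    if (!file.exists(lf)) abort(paste("missing label table for", img))
    out[[img]] <- load_annotation(mf, lf, img, geom)
  }
  out
}

load_saliency_dir <- function(dir, geom) {
  files <- list.files(dir, pattern = "_saliency\\.txt$", full.names = TRUE)
  out <- list()
  for (f in files) {
    img <- sub("_saliency\\.txt$", "", basename(f))
    out[[img]] <- read_saliency(f, img, geom)
  }
  out
}

#' Run the full analysis pipeline
#'
#' parse (or ingest) -> exclusion cascade -> annotate -> event series ->
#' mixed models, binned ANOVAs and Holm post hoc tests. Deterministic
#' given identical inputs and seed. With `out_dir` set, writes the
#' exclusion report, the series table, per-model coefficient tables (TSV +
#' JSON), ANOVA and post hoc tables, and a plain-text summary report.
#'
#' @param cfg A [pipeline_config()] (or path to its YAML file).
#' @return List: `events` (flagged), `exclusions`, `series`, `lmm` (nested
#'   by response and contrast), `aux_amplitude` (the post hoc model of
#'   target amplitude on onset time and angle), `anovas` and `posthocs`
#'   (face contrast, per response and control).
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  set.seed(cfg$seed)

  # --- parse -----------------------------------------------------------
  events <- cfg$events
  if (is.character(events)) events <- read_gaze_events(events)
  if (is.null(events)) {
    samples <- cfg$samples
    if (is.character(samples)) samples <- read_gaze_samples(samples)
    if (is.null(samples)) abort("stage parse: no events or samples supplied")
    events <- detect_events(samples)
  }
  if (nrow(events) == 0) abort("stage parse: empty event table")

  # --- filter ----------------------------------------------------------
  events <- apply_cascade(events, geom = cfg$geom)
  report <- exclusion_report(events)

  # --- annotate + series ----------------------------------------------
  annotations <- cfg$annotations
  if (is.character(annotations)) {
    annotations <- load_annotation_dir(annotations, cfg$geom)
  }
  if (is.null(annotations)) abort("stage annotate: no annotations supplied")
  saliency <- cfg$saliency
  if (is.character(saliency)) saliency <- load_saliency_dir(saliency, cfg$geom)
  series <- build_series(events, annotations, radius = cfg$radius)
  if (nrow(series) == 0) abort("stage series: no valid event series")
  series <- featurize(series, saliency, radius = cfg$radius)

  # --- stats -----------------------------------------------------------
  lmm <- list()
  for (resp in cfg$responses) {
    for (ctr in cfg$contrasts) {
      tab <- standardize(series, response = resp, contrast = ctr)
      lmm[[resp]][[ctr]] <- if (cfg$select_models) {
        aic_model_sweep(tab, delta_max = cfg$delta_max)
      } else {
        fit_lmm(tab, random = c(subject = "intercept", image = "intercept",
                                object = "intercept"))
      }
    }
  }
  aux_tab <- standardize(series, response = "target_amplitude",
                         contrast = "face")
  aux <- fit_lmm(aux_tab, fixed = c("onset_time", "angle"),
                 random = c(subject = "intercept", image = "intercept",
                            object = "intercept"))

  anovas <- list(); posthocs <- list()
  for (resp in cfg$responses) {
    for (ctl in cfg$anova_controls) {
      if (all(is.na(series[[ctl]]))) next
      res <- try(binned_anova(series, ctl, response = resp), silent = TRUE)
      if (inherits(res, "try-error")) next
      anovas[[resp]][[ctl]] <- res
      ph <- try(suppressWarnings(
        holm_posthoc(series, ctl, response = resp, alpha = cfg$alpha)),
        silent = TRUE)
      if (!inherits(ph, "try-error")) posthocs[[resp]][[ctl]] <- ph
    }
  }

  out <- list(events = events, exclusions = report, series = series,
              lmm = lmm, aux_amplitude = aux, anovas = anovas,
              posthocs = posthocs)
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(out, cfg$out_dir)
  out
}

# AIC-difference model sweep: three random structures at the full fixed
# part, plus leave-one-out fixed parts at the full random structure; the
# simplest model within delta_max of the minimum AIC is selected
aic_model_sweep <- function(tab, delta_max = 2) {
  preds <- attr(tab, "predictors")
  fits <- list(
    fit_lmm(tab, random = c(subject = "slope", image = "slope",
                            object = "intercept")),
    fit_lmm(tab, random = c(subject = "slope", image = "intercept",
                            object = "intercept")),
    fit_lmm(tab, random = c(subject = "intercept", image = "intercept",
                            object = "intercept")))
  for (drop in preds) {
    fits[[length(fits) + 1]] <-
      fit_lmm(tab, fixed = setdiff(preds, drop),
              random = c(subject = "slope", image = "slope",
                         object = "intercept"))
  }
  aic_delta_select(fits, delta_max = delta_max)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_exclusion_report(res$exclusions,
                         file.path(out_dir, "exclusion_report.tsv"),
                         file.path(out_dir, "exclusion_report.json"))
  write_series(res$series, file.path(out_dir, "series.tsv"))
  lines <- character()
  for (resp in names(res$lmm)) {
    for (ctr in names(res$lmm[[resp]])) {
      fit <- res$lmm[[resp]][[ctr]]
      base <- sprintf("lmm_%s_%s", resp, ctr)
      write_results(fit, file.path(out_dir, paste0(base, ".tsv")),
                    file.path(out_dir, paste0(base, ".json")))
      co <- tidy(fit)
      lines <- c(lines, sprintf("[%s ~ %s] n = %d, AIC = %.1f", resp, ctr,
                                fit$n, fit$aic),
                 sprintf("  %-18s b = %+.3f (SE %.3f), t(%d) = %.2f, p = %.3g",
                         co$term, co$estimate, co$std.error, co$df,
                         co$statistic, co$p.value), "")
    }
  }
  write_results(res$aux_amplitude,
                file.path(out_dir, "lmm_target_amplitude_aux.tsv"),
                file.path(out_dir, "lmm_target_amplitude_aux.json"))
  for (resp in names(res$anovas)) {
    for (ctl in names(res$anovas[[resp]])) {
      write_results(res$anovas[[resp]][[ctl]],
                    file.path(out_dir, sprintf("anova_%s_%s.tsv", resp, ctl)))
      ph <- res$posthocs[[resp]][[ctl]]
      if (!is.null(ph)) {
        write_results(ph,
                      file.path(out_dir,
                                sprintf("posthoc_%s_%s.tsv", resp, ctl)))
      }
    }
  }
  writeLines(lines, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' Simulate, analyse and compare against planted ground truth
#'
#' One-command recovery loop: generate synthetic scenes and gaze with
#' planted face effects, run the cascade, series construction and
#' mixed-effects fits, and compare the recovered standardized face betas
#' against the planted values. A replicate recovers an effect when the
#' planted value lies inside the estimate's 95% confidence interval; the
#' overall check passes when CI coverage is at least `min_coverage` and
#' the mean bias across replicates is at most `tol_bias` for both
#' responses.
#'
#' @param cfg A [synth_config()].
#' @param n_replicates Number of replicate seeds (`cfg$seed + 0:(k-1)`).
#' @param truth_velocity,truth_duration Reference planted values compared
#'   against (defaults: the generator's own configured effects; override
#'   to verify that a mis-specified truth fails).
#' @param tol_bias Mean-bias tolerance, SD units.
#' @param min_coverage Minimum fraction of replicates whose 95% CI covers
#'   the truth.
#' @return A tibble with one row per replicate and response (`estimate`,
#'   `std.error`, `conf.low`, `conf.high`, `truth`, `covered`, `bias`,
#'   `p.value`, `n_series`), with attributes `pass`, `mean_bias` and
#'   `coverage`.
#' @export
simulate_and_check <- function(cfg, n_replicates = 1,
                               truth_velocity = cfg$face_velocity_boost,
                               truth_duration =
                                 cfg$duration_model$face_shortening,
                               tol_bias = 0.02, min_coverage = 0.85) {
  rows <- list()
  for (r in seq_len(n_replicates)) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + (r - 1L) * 1000L
    sim <- generate_gaze(cfg_r)
    res <- analyze_simulation(sim, cfg_r)
    truth <- c(peak_velocity = truth_velocity,
               intermediate_duration = truth_duration)
    for (resp in names(res)) {
      co <- tidy(res[[resp]])
      fb <- co[co$term == "category", ]
      ci <- fb$estimate + c(-1, 1) * qt(0.975, fb$df) * fb$std.error
      tr <- unname(truth[resp])
      rows[[length(rows) + 1]] <- tibble::tibble(
        replicate = r, response = resp, estimate = fb$estimate,
        std.error = fb$std.error, conf.low = ci[1], conf.high = ci[2],
        truth = tr, covered = tr >= ci[1] & tr <= ci[2],
        bias = fb$estimate - tr,
        p.value = fb$p.value, n_series = res[[resp]]$n)
    }
  }
  out <- dplyr::bind_rows(rows)
  smry <- out |>
    dplyr::group_by(.data$response) |>
    dplyr::summarise(mean_bias = mean(.data$bias),
                     coverage = mean(.data$covered),
                     se_mean = mean(.data$std.error) /
                       sqrt(dplyr::n()), .groups = "drop")
  # the bias gate cannot be tighter than the Monte-Carlo error of the mean
  pass <- all(abs(smry$mean_bias) <= pmax(tol_bias, 2 * smry$se_mean)) &&
    all(smry$coverage >= min_coverage)
  attr(out, "summary") <- smry
  attr(out, "pass") <- pass
  out
}

# cascade -> series -> primary LMMs on a generated dataset
analyze_simulation <- function(sim, cfg) {
  geom <- sim$scenes$geom
  events <- apply_cascade(sim$events, geom = geom)
  series <- build_series(events, sim$scenes$annotations)
  series <- featurize(series, sim$scenes$saliency)
  out <- list()
  for (resp in c("peak_velocity", "intermediate_duration")) {
    tab <- standardize(series, response = resp, contrast = "face")
    out[[resp]] <- fit_lmm(tab,
                           random = c(subject = "intercept",
                                      image = "intercept",
                                      object = "intercept"))
  }
  out
}

#' Reproduce the external free-viewing analysis from a local data deposit
#'
#' Runs the full pipeline against a locally downloaded copy of the
#' original free-viewing dataset: a directory that must contain
#' `events.tsv` (vendor-parsed events in the [read_gaze_events()] schema,
#' with `image_id`), an `annotations/` subdirectory of
#' `<image>_mask.txt` / `<image>_labels.tsv` pairs combining the
#' scene-object masks with the person-region refinements, and optionally
#' `saliency/` with `<image>_saliency.txt` maps. Returns the event-series
#' counts per target category and the fitted face/body betas for both
#' responses — the quantities reported by the original study.
#'
#' @param deposit_dir Directory with the prepared deposit.
#' @param geom Stimulus geometry of the recordings.
#' @return List with `counts` (named: face, inanimate, body) and `betas`
#'   (tibble: response, contrast, estimate, se, t, p).
#' @export
reproduce_external <- function(deposit_dir,
                               geom = screen_geometry(800, 600)) {
  if (!dir.exists(deposit_dir)) {
    abort(paste0("external deposit not found at '", deposit_dir, "'; ",
                 "download the anonymized gaze data and scene masks and ",
                 "prepare them in the documented layout"))
  }
  cfg <- pipeline_config(
    events = file.path(deposit_dir, "events.tsv"),
    annotations = file.path(deposit_dir, "annotations"),
    saliency = if (dir.exists(file.path(deposit_dir, "saliency")))
      file.path(deposit_dir, "saliency"),
    geom = geom, select_models = TRUE)
  res <- run_pipeline(cfg)
  counts <- table(res$series$target_category)
  betas <- list()
  for (resp in names(res$lmm)) {
    for (ctr in names(res$lmm[[resp]])) {
      co <- tidy(res$lmm[[resp]][[ctr]])
      fb <- co[co$term == "category", ]
      betas[[length(betas) + 1]] <- tibble::tibble(
        response = resp, contrast = ctr, estimate = fb$estimate,
        std.error = fb$std.error, statistic = fb$statistic,
        p.value = fb$p.value)
    }
  }
  list(counts = c(face = unname(counts["face"]),
                  inanimate = unname(counts["inanimate"]),
                  body = unname(counts["body"])),
       betas = dplyr::bind_rows(betas))
}
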