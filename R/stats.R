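#' Standardize an event-series table for mixed-effects modeling
#'
#' Continuous predictors are z-scored over all retained series. The
#' velocity response is z-scored; the duration response is natural-log
#' transformed first (fixation durations are right-skewed) and then
#' z-scored. The semantic category contrast is dummy coded with the tested
#' category (faces or bodies) as 1 and inanimate objects, the reference
#' category, as 0; series of other categories are dropped.
#'
#' @param series Featurized series tibble (see [featurize()]).
#' @param response `"peak_velocity"` or `"intermediate_duration"`.
#' @param contrast Category tested against inanimate objects.
#' @param log_duration Log-transform the duration response before
#'   z-scoring.
#' @return A model table: `y` (standardized response), `category` (0/1
#'   dummy), z-scored predictor columns, and `subject`, `image`, `object`
#'   grouping factors. Salience columns that are entirely missing are
#'   dropped (with a message). The set of fixed predictors actually
#'   available is recorded in `attr(, "predictors")`.
#' @export
standardize <- function(series, response = c("peak_velocity",
                                             "intermediate_duration",
                                             "target_amplitude"),
                        contrast = c("face", "body"),
                        log_duration = TRUE) {
  response <- match.arg(response)
  contrast <- match.arg(contrast)
  d <- series[series$target_category %in% c(contrast, "inanimate"), ,
              drop = FALSE]
  if (nrow(d) < 2) abort("need at least 2 series after category filtering")

  preds <- setdiff(
    c("target_amplitude", "incoming_amplitude", "target_size",
      "onset_time", "angle", "gbvs_intermediate", "gbvs_target"),
    response)
  keep <- character()
  out <- tibble::tibble(
    category = as.numeric(d$target_category == contrast),
    subject = factor(d$subject_id),
    image = factor(d$image_id),
    object = factor(paste(d$image_id, d$visual_object_id, sep = ":"))
  )
  for (p in preds) {
    v <- d[[p]]
    if (all(is.na(v))) {
      message("predictor ", p, " is entirely missing and was dropped")
      next
    }
    out[[p]] <- zscore(v, p)
    keep <- c(keep, p)
  }
  y <- d[[response]]
  if (response == "intermediate_duration" && log_duration) {
    if (any(y <= 0, na.rm = TRUE)) abort("durations must be positive to log")
    y <- log(y)
  }
  out$y <- zscore(y, response)
  attr(out, "predictors") <- keep
  attr(out, "response") <- response
  attr(out, "contrast") <- contrast
  out
}

zscore <- function(v, name) {
  s <- sd(v, na.rm = TRUE)
  if (is.na(s) || s == 0) {
    abort(paste0("cannot z-score '", name, "': zero variance"))
  }
  (v - mean(v, na.rm = TRUE)) / s
}

#' Fit a linear mixed-effects model of a standardized gaze response
#'
#' Fits by maximum likelihood (not REML) so that AIC values are comparable
#' across fixed-effect structures. Random effects are specified per
#' grouping factor as `"intercept"`, `"slope"` (random intercept plus a
#' random slope on the category dummy) or `"none"`; visual objects are
#' nested in images by construction of the `object` factor and only take
#' an intercept (an object is either a face or an inanimate object).
#' Fixed-effect p-values use the residual-degrees-of-freedom approximation
#' `df = n - p`.
#'
#' @param table Model table from [standardize()].
#' @param fixed Character vector of fixed predictors (besides `category`);
#'   defaults to every predictor available in `table`.
#' @param random Named character vector for `subject`, `image`, `object`.
#' @param include_category Keep the category dummy in the fixed part.
#' @return A `gaze_lmm` object; see [tidy.gaze_lmm()] and
#'   [glance.gaze_lmm()].
#' @export
fit_lmm <- function(table,
                    fixed = attr(table, "predictors"),
                    random = c(subject = "slope", image = "slope",
                               object = "intercept"),
                    include_category = TRUE) {
  if (is.null(fixed)) {
    fixed <- intersect(
      c("target_amplitude", "incoming_amplitude", "target_size",
        "onset_time", "angle", "gbvs_intermediate", "gbvs_target"),
      names(table))
  }
  fix_terms <- c(if (include_category) "category", fixed)
  re_terms <- character()
  for (g in names(random)) {
    re_terms <- c(re_terms, switch(random[[g]],
      slope = sprintf("(1 + category | %s)", g),
      intercept = sprintf("(1 | %s)", g),
      none = NULL,
      abort("random spec must be 'slope', 'intercept' or 'none'")))
  }
  if (length(re_terms) == 0) abort("at least one random term is required")
  fml <- stats::as.formula(paste(
    "y ~", paste(c(fix_terms, re_terms), collapse = " + ")))

  d <- table[complete.cases(table[, c("y", fix_terms)]), , drop = FALSE]
  fit <- withCallingHandlers(
    lme4::lmer(fml, data = d, REML = FALSE,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular =
                                             lme4::.makeCC("ignore", 1e-4))),
    warning = function(w) invokeRestart("muffleWarning"))
  converged <- length(fit@optinfo$conv$lme4) == 0

  b <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  n <- nrow(d)
  p <- length(b)
  df <- n - p
  tval <- b / se
  coefs <- tibble::tibble(
    term = names(b), estimate = unname(b), std.error = unname(se),
    statistic = unname(tval), df = df,
    p.value = 2 * pt(-abs(unname(tval)), df))

  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(
    list(model = fit, coefficients = coefs, aic = AIC(fit),
         loglik = as.numeric(logLik(fit)), n = n, n_par = attr(logLik(fit), "df"),
         df = df, converged = converged, formula = fml,
         random = random, fixed = fix_terms, varcorr = vc,
         response = attr(table, "response"),
         contrast = attr(table, "contrast")),
    class = "gaze_lmm")
}

#' @export
print.gaze_lmm <- function(x, ...) {
  cat(sprintf("<gaze_lmm> %s (n = %d, AIC = %.1f%s)\n",
              paste(trimws(deparse(x$formula)), collapse = " "),
              x$n, x$aic,
              if (!x$converged) ", NOT converged" else ""))
  print(as.data.frame(x$coefficients), digits = 3)
  invisible(x)
}

#' Tidy a fitted gaze mixed model
#'
#' @param x A `gaze_lmm`.
#' @param ... Unused.
#' @return Tibble of fixed effects: `term`, `estimate` (standardized
#'   units), `std.error`, `statistic` (t), `df`, `p.value`.
#' @method tidy gaze_lmm
#' @export
tidy.gaze_lmm <- function(x, ...) x$coefficients

#' @rdname tidy.gaze_lmm
#' @return For `glance`: a one-row tibble with `n`, `n_par`, `AIC`,
#'   `logLik` and `converged`.
#' @method glance gaze_lmm
#' @export
glance.gaze_lmm <- function(x, ...) {
  tibble::tibble(n = x$n, n_par = x$n_par, AIC = x$aic, logLik = x$loglik,
                 converged = x$converged)
}

#' Select the simplest model on par with the best by the AIC difference rule
#'
#' Computes `delta_i = AIC_i - AIC_min` over all converged candidates and,
#' among candidates with `delta_i < delta_max`, returns the one with the
#' fewest parameters (ties broken by listed order). Non-converged
#' candidates are skipped.
#'
#' @param candidates List of `gaze_lmm` fits (or any objects with `aic`,
#'   `n_par` and `converged` fields).
#' @param delta_max AIC-difference threshold (default 2).
#' @return The chosen fit, with the comparison table in
#'   `attr(, "aic_table")`.
#' @export
aic_delta_select <- function(candidates, delta_max = 2) {
  ok <- vapply(candidates, function(f) isTRUE(f$converged), logical(1))
  if (!any(ok)) abort("no converged candidate models")
  aics <- vapply(candidates, function(f) f$aic, numeric(1))
  npar <- vapply(candidates, function(f) f$n_par, numeric(1))
  delta <- aics - min(aics[ok])
  elig <- ok & delta < delta_max
  pick <- which(elig)[order(npar[elig])][1]
  tab <- tibble::tibble(candidate = seq_along(candidates), AIC = aics,
                        delta = delta, n_par = npar, converged = ok,
                        chosen = seq_along(candidates) == pick)
  chosen <- candidates[[pick]]
  attr(chosen, "aic_table") <- tab
  chosen
}

#' Default bin specifications for the binned interaction ANOVAs
#'
#' Bin widths follow the analysis design: relative angle in 15 bins of 12
#' degrees; target and incoming saccade amplitude in 14 bins of 1 dva;
#' target-saccade onset in 13 bins of 200 ms (starting at the 100 ms
#' early-onset cutoff); target size in 10 bins of 10% image area; salience
#' sums in 10 bins of 40 arbitrary units.
#'
#' @param predictor Predictor name as in the series table.
#' @return Numeric vector of bin edges.
#' @export
bin_spec <- function(predictor) {
  switch(predictor,
    angle = seq(0, 180, by = 12),
    target_amplitude = seq(0, 14, by = 1),
    incoming_amplitude = seq(0, 14, by = 1),
    onset_time = seq(100, 2700, by = 200),
    target_size = seq(0, 100, by = 10),
    gbvs_intermediate = seq(0, 400, by = 40),
    gbvs_target = seq(0, 400, by = 40),
    abort(paste("no default bin specification for", predictor)))
}

#' Two-way ANOVA of a response on semantic category by a binned control
#'
#' Bins the control predictor at the given edges (values outside the edges
#' are dropped), crosses the bins with semantic target category and fits a
#' two-way fixed-effects ANOVA with interaction on the series-level
#' response. Effect sizes are eta squared (term sum of squares over total).
#' Bins with no data in either category are dropped with a warning.
#'
#' @param series Featurized series tibble.
#' @param control Control predictor name.
#' @param bins Bin edges; defaults to [bin_spec()].
#' @param response Response column name.
#' @param categories Two category levels; the first is the reference.
#' @return A `gaze_anova` object: ANOVA table plus cell means/SE.
#' @export
binned_anova <- function(series, control, bins = bin_spec(control),
                         response = "peak_velocity",
                         categories = c("inanimate", "face")) {
  d <- series[series$target_category %in% categories, , drop = FALSE]
  d$bin <- cut(d[[control]], breaks = bins, include.lowest = FALSE,
               right = TRUE)
  d <- d[!is.na(d$bin) & !is.na(d[[response]]), , drop = FALSE]
  tab <- table(d$bin, d$target_category)
  nonempty <- rowSums(tab > 0) == length(categories)
  if (sum(nonempty) < 2) abort("fewer than 2 bins with data in all categories")
  if (any(!nonempty)) {
    warn(sprintf("dropping %d bin(s) with an empty cell", sum(!nonempty)))
    d <- d[d$bin %in% rownames(tab)[nonempty], , drop = FALSE]
  }
  d$bin <- droplevels(d$bin)
  d$category <- factor(d$target_category, levels = categories)
  fml <- stats::as.formula(paste(response, "~ category * bin"))
  fit <- aov(fml, data = d)
  sm <- summary(fit)[[1]]
  terms <- trimws(rownames(sm))
  total_ss <- sum(sm[["Sum Sq"]])
  anova_tab <- tibble::tibble(
    term = c("category", "bin", "category:bin", "residuals"),
    df = sm[["Df"]], sumsq = sm[["Sum Sq"]],
    statistic = sm[["F value"]], p.value = sm[["Pr(>F)"]],
    eta_sq = sm[["Sum Sq"]] / total_ss)

  cells <- d |>
    dplyr::group_by(.data$bin, .data$category) |>
    dplyr::summarise(n = dplyr::n(),
                     mean = mean(.data[[response]]),
                     se = sd(.data[[response]]) / sqrt(dplyr::n()),
                     .groups = "drop")
  structure(list(table = anova_tab, cells = cells, control = control,
                 response = response, bins = bins, n = nrow(d)),
            class = "gaze_anova")
}

#' @export
print.gaze_anova <- function(x, ...) {
  cat(sprintf("<gaze_anova> %s ~ category x binned %s (n = %d)\n",
              x$response, x$control, x$n))
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' @method tidy gaze_anova
#' @export
tidy.gaze_anova <- function(x, ...) x$table

#' @method glance gaze_anova
#' @export
glance.gaze_anova <- function(x, ...) {
  inter <- x$table[x$table$term == "category:bin", ]
  tibble::tibble(n = x$n, f_interaction = inter$statistic,
                 p_interaction = inter$p.value, eta_sq = inter$eta_sq)
}

#' Holm-Bonferroni corrected paired post hoc tests per bin
#'
#' For every bin of a control predictor, aggregates the response to
#' subject-level means per category, pairs them within subject and runs a
#' paired t-test over subjects contributing both categories. The family of
#' per-bin p-values is corrected with the Holm step-down procedure at
#' family-wise alpha. Bins with fewer than `min_pairs` complete pairs are
#' dropped with a warning.
#'
#' @inheritParams binned_anova
#' @param alpha Family-wise error rate.
#' @param min_pairs Minimum subjects contributing both categories per bin.
#' @return A `gaze_posthoc` tibble-backed object: per bin `n_pairs`,
#'   `mean_diff` (second minus first category), `statistic`, `df`,
#'   `p.value`, `p.holm` and `significant`.
#' @export
holm_posthoc <- function(series, control, bins = bin_spec(control),
                         response = "peak_velocity",
                         categories = c("inanimate", "face"),
                         alpha = 0.05, min_pairs = 2) {
  d <- series[series$target_category %in% categories, , drop = FALSE]
  d$bin <- cut(d[[control]], breaks = bins, include.lowest = FALSE,
               right = TRUE)
  d <- d[!is.na(d$bin) & !is.na(d[[response]]), , drop = FALSE]
  subj_means <- d |>
    dplyr::group_by(.data$bin, .data$subject_id, .data$target_category) |>
    dplyr::summarise(m = mean(.data[[response]]), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "target_category", values_from = "m")
  rows <- list()
  dropped <- 0
  for (b in levels(d$bin)) {
    sb <- subj_means[subj_means$bin == b, , drop = FALSE]
    sb <- sb[complete.cases(sb[, categories]), , drop = FALSE]
    if (nrow(sb) < min_pairs) { dropped <- dropped + 1; next }
    diffs <- sb[[categories[2]]] - sb[[categories[1]]]
    tt <- t.test(diffs)
    rows[[b]] <- tibble::tibble(
      bin = b, n_pairs = nrow(sb), mean_diff = mean(diffs),
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p.value = tt$p.value)
  }
  if (dropped > 0) {
    warn(sprintf("dropping %d bin(s) with fewer than %d complete pairs",
                 dropped, min_pairs))
  }
  if (length(rows) == 0) abort("no bin has enough complete pairs")
  res <- dplyr::bind_rows(rows)
  res$p.holm <- p.adjust(res$p.value, method = "holm")
  res$significant <- res$p.holm < alpha
  structure(res, class = c("gaze_posthoc", class(res)),
            control = control, response = response, alpha = alpha)
}

#' @method tidy gaze_posthoc
#' @export
tidy.gaze_posthoc <- function(x, ...) tibble::as_tibble(x)

#' Export model results as TSV and JSON
#'
#' @param x A `gaze_lmm`, `gaze_anova` or `gaze_posthoc` object.
#' @param path_tsv,path_json Output paths (either may be `NULL`).
#' @export
write_results <- function(x, path_tsv = NULL, path_json = NULL) {
  tab <- tidy(x)
  if (!is.null(path_tsv)) readr::write_tsv(tab, path_tsv, progress = FALSE)
  if (!is.null(path_json)) {
    jsonlite::write_json(tab, path_json, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(tab)
}
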