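#' Main-sequence plot: peak velocity against amplitude by target category
#'
#' Binned means (1 dva bins) with standard errors over the series-level
#' scatter, separating face- and inanimate-object-directed saccades.
#'
#' @param series Featurized series tibble.
#' @param max_amplitude Upper amplitude limit for the binned overlay, dva.
#' @return A ggplot object.
#' @export
plot_main_sequence <- function(series, max_amplitude = 14) {
  d <- series[series$target_category %in% c("face", "inanimate"), ,
              drop = FALSE]
  d$bin <- cut(d$target_amplitude, seq(0, max_amplitude, 1))
  binned <- d |>
    dplyr::filter(!is.na(.data$bin)) |>
    dplyr::group_by(.data$bin, .data$target_category) |>
    dplyr::summarise(
      amplitude = mean(.data$target_amplitude),
      mean_pv = mean(.data$peak_velocity),
      se = sd(.data$peak_velocity) / sqrt(dplyr::n()), .groups = "drop")
  ggplot2::ggplot(binned,
                  ggplot2::aes(x = .data$amplitude, y = .data$mean_pv,
                               colour = .data$target_category)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_pv - .data$se,
                                          ymax = .data$mean_pv + .data$se)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "target saccade amplitude (dva)",
                  y = "peak velocity (deg/s)", colour = "target") +
    ggplot2::theme_minimal()
}

#' @method autoplot gaze_anova
#' @export
autoplot.gaze_anova <- function(object, ...) {
  ggplot2::ggplot(object$cells,
                  ggplot2::aes(x = .data$bin, y = .data$mean,
                               colour = .data$category,
                               group = .data$category)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = paste("binned", object$control), y = object$response,
                  colour = "target") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @method autoplot gaze_posthoc
#' @export
autoplot.gaze_posthoc <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$sig <- ifelse(d$significant, "*", "")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$mean_diff)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = .data$sig),
                       vjust = -0.3, size = 6, colour = "red") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = paste("binned", attr(object, "control")),
                  y = "category difference",
                  title = "Holm-corrected paired differences per bin") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @method autoplot gaze_lmm
#' @export
autoplot.gaze_lmm <- function(object, ...) {
  co <- tidy(object)
  co <- co[co$term != "(Intercept)", , drop = FALSE]
  co$term <- factor(co$term, levels = rev(co$term))
  ggplot2::ggplot(co, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$estimate - 1.96 * .data$std.error,
                   xmax = .data$estimate + 1.96 * .data$std.error)) +
    ggplot2::labs(x = "standardized estimate (SD units)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Exclusion-cascade summary plot
#'
#' @param report Tibble from [exclusion_report()].
#' @return A ggplot object.
#' @export
plot_exclusions <- function(report) {
  d <- report[report$rule_id != "any", , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rule_id,
                                  y = 100 * .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of events flagged") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
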