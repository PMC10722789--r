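#' Group-comparison figure for the behavioral indicators
#'
#' Mean +/- SE of each indicator per diagnostic group.
#'
#' @param analysis A per-participant tibble from [simulate_cohort()] or
#'   `run$analysis`.
#' @return A ggplot object.
#' @export
plot_indicator_groups <- function(analysis) {
  long <- tidyr::pivot_longer(
    dplyr::select(analysis, "group", dplyr::all_of(INDICATOR_COLS)),
    -"group", names_to = "indicator", values_to = "value")
  long$indicator <- factor(toupper(long$indicator), levels = toupper(INDICATOR_COLS))
  summ <- long |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$group, .data$indicator) |>
    dplyr::summarise(mean = mean(.data$value),
                     se = stats::sd(.data$value) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(.data$indicator, .data$mean, fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se, ymax = .data$mean + .data$se),
      position = ggplot2::position_dodge(0.8), width = 0.25) +
    ggplot2::labs(x = NULL, y = "Proportion of session", fill = "Group") +
    ggplot2::theme_minimal()
}

#' Band-PSD group figure
#'
#' Analysis-scale theta and alpha band PSD per diagnostic group.
#'
#' @inheritParams plot_indicator_groups
#' @return A ggplot object.
#' @export
plot_band_psd_groups <- function(analysis) {
  long <- tidyr::pivot_longer(
    dplyr::select(analysis, "group", dplyr::all_of(c("theta", "alpha"))),
    -"group", names_to = "band", values_to = "value")
  summ <- long |>
    dplyr::group_by(.data$group, .data$band) |>
    dplyr::summarise(mean = mean(.data$value),
                     se = stats::sd(.data$value) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(.data$band, .data$mean, fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se, ymax = .data$mean + .data$se),
      position = ggplot2::position_dodge(0.8), width = 0.25) +
    ggplot2::labs(x = NULL, y = "Band PSD (analysis scale)", fill = "Group") +
    ggplot2::theme_minimal()
}
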