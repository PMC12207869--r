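#' Skin-temperature trace figure
#'
#' Example traces over the study, coloured by the daytime condition, with
#' night shading -- the standard visual check that the generator and the
#' segmentation behave.
#'
#' @param ds a `torpor_dataset`.
#' @param bird_ids birds to draw (default: first two).
#' @param windows a [phase_windows()] (for night shading).
#' @return a ggplot object.
#' @export
plot_trace <- function(ds, bird_ids = head(unique(ds$ts$bird_id), 2),
                       windows = phase_windows()) {
  ts <- ds$ts |> filter(.data$bird_id %in% bird_ids, !is.na(.data$ts_c))
  day_cond <- ds$schedule |> select("site", "date", "condition")
  ts$date <- date_of(ts$time)
  ts <- left_join(ts, day_cond, by = c("site", "date"))
  nights <- ds$schedule |>
    distinct(.data$date) |>
    mutate(start = at_hour(.data$date, windows$rest_start),
           end = at_hour(.data$date + 1, windows$rest_end))
  ggplot2::ggplot(ts, ggplot2::aes(x = .data$time, y = .data$ts_c)) +
    ggplot2::geom_rect(data = nights, inherit.aes = FALSE,
                       ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = -Inf, ymax = Inf),
                       fill = "grey85", alpha = 0.5) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$condition), size = 0.5) +
    ggplot2::facet_wrap(~bird_id, ncol = 1) +
    ggplot2::scale_colour_manual(values = c(control = "black",
                                            treatment = "#3366cc"),
                                 na.value = "grey50") +
    ggplot2::labs(x = NULL, y = "Skin temperature (°C)",
                  colour = "Daytime condition") +
    ggplot2::theme_minimal()
}

#' Torpor depth and duration distributions by condition
#'
#' Boxplots with raw bird-nights overlaid, for nightly minimum skin
#' temperature and torpor bout duration.
#'
#' @param nights included bird-night table with metrics.
#' @return a ggplot object.
#' @export
plot_condition_distributions <- function(nights) {
  long <- nights |>
    filter(.data$included) |>
    select("condition", "min_rest_ts", "torpor_duration_h") |>
    tidyr::pivot_longer(c("min_rest_ts", "torpor_duration_h"),
                        names_to = "metric") |>
    mutate(metric = factor(.data$metric,
                           levels = c("min_rest_ts", "torpor_duration_h"),
                           labels = c("Minimum nightly Ts (°C)",
                                      "Torpor duration (h)")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.35, size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
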