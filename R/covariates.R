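#' Join model covariates to the analysis records
#'
#' Builds the model-ready night and day tables on the study's exact
#' averaging windows:
#' * nights get `ta` = 24-h mean air temperature from 07:00 of the preceding
#'   active-phase to 07:00 after the rest-phase, and `wind` = the maximum
#'   daily wind speed of the preceding daytime's date;
#' * days get `ta` = mean air temperature over the active phase
#'   (07:00-17:00 of the same date) and that date's `wind`.
#'
#' Body mass at capture (`mass`, g) and `sex` come from the metadata; birds
#' with either missing are dropped from the model tables with a message.
#' `condition` keeps control as the reference level so treatment
#' coefficients read as treatment minus control. Records whose weather
#' window has under 90% coverage are excluded with reason
#' `low_weather_coverage`.
#'
#' @param nights bird-night table with metrics.
#' @param days bird-day table from [daily_summaries()].
#' @param ds the `torpor_dataset` (weather + metadata source).
#' @param windows a [phase_windows()].
#' @param min_coverage minimum fraction of weather grid slots per window.
#' @return list with model-ready `nights` and `days` tibbles.
#' @export
join_covariates <- function(nights, days, ds, windows = phase_windows(),
                            min_coverage = 0.9) {
  interval <- ds$config$sample_interval_min
  meta <- ds$birds[, c("bird_id", "sex", "body_mass_g")]
  bad_meta <- meta$bird_id[is.na(meta$sex) | is.na(meta$body_mass_g)]
  if (length(bad_meta)) {
    message("bird(s) with missing mass/sex dropped from models: ",
            paste(bad_meta, collapse = ", "))
  }

  h0 <- windows$active_start  # covariate windows anchor at the active start
  ta_day <- function(dates) {
    vapply(as.numeric(unique(dates)), function(d) {
      d <- as.Date(d, origin = "1970-01-01")
      ta_window_mean(ds$weather, at_hour(d, h0), at_hour(d, windows$active_end),
                     min_coverage, interval)
    }, numeric(1)) |>
      setNames(as.character(unique(dates)))
  }
  ta_24 <- function(dates) {
    vapply(as.numeric(unique(dates)), function(d) {
      d <- as.Date(d, origin = "1970-01-01")
      ta_window_mean(ds$weather, at_hour(d, h0), at_hour(d + 1, h0),
                     min_coverage, interval)
    }, numeric(1)) |>
      setNames(as.character(unique(dates)))
  }

  wind <- ds$weather$wind
  nights_out <- nights |>
    mutate(ta = unname(ta_24(.data$night_date)[as.character(.data$night_date)])) |>
    left_join(wind, by = c("night_date" = "date")) |>
    rename(wind = "wind_max_kmh") |>
    left_join(meta, by = "bird_id") |>
    rename(mass = "body_mass_g") |>
    filter(!.data$bird_id %in% bad_meta)
  nights_out$exclusion_reason <- ifelse(
    nights_out$included & (is.na(nights_out$ta) | is.na(nights_out$wind)),
    "low_weather_coverage", nights_out$exclusion_reason)
  nights_out$included <- nights_out$included &
    !is.na(nights_out$ta) & !is.na(nights_out$wind)

  days_out <- days |>
    mutate(ta = unname(ta_day(.data$date)[as.character(.data$date)])) |>
    left_join(wind, by = "date") |>
    rename(wind = "wind_max_kmh") |>
    left_join(meta, by = "bird_id") |>
    rename(mass = "body_mass_g") |>
    filter(!.data$bird_id %in% bad_meta)
  days_out$exclusion_reason <- ifelse(
    days_out$included & (is.na(days_out$ta) | is.na(days_out$wind)),
    "low_weather_coverage", days_out$exclusion_reason)
  days_out$included <- days_out$included &
    !is.na(days_out$ta) & !is.na(days_out$wind)

  stopifnot(!anyDuplicated(nights_out[, c("bird_id", "night_date")]),
            !anyDuplicated(days_out[, c("bird_id", "date")]))
  list(nights = nights_out, days = days_out)
}
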