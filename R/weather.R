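#' Simulate the weather series for a scenario
#'
#' Air temperature follows a diel sinusoid interpolating between a drawn daily
#' minimum (trough near 06:00) and maximum (peak near 14:00), with small AR(1)
#' noise on the sampling grid. One daily maximum wind speed is drawn per date
#' and clamped below at `wind_floor` km/h.
#'
#' The series extends one day past the study so that the final night's
#' rest-phase (through 08:00) and its 24-h covariate window are fully covered.
#'
#' @param cfg a [scenario_config()].
#' @param seed optional seed; when `NULL` the current RNG stream is used (as
#'   inside [simulate_scenario()]). Defaults to `cfg$rng_seed` when called
#'   standalone.
#' @return an object of class `weather_series`: list with
#'   `ta` (tibble `time`, `ta_c`), `wind` (tibble `date`, `wind_max_kmh`) and
#'   attribute `ref_ta`, the grand-mean air temperature over study days used
#'   as the reference for all planted slope terms.
#' @export
simulate_weather <- function(cfg, seed = cfg$rng_seed) {
  validate_scenario(cfg)
  if (!is.null(seed)) set.seed(seed)
  n_days_total <- cfg$n_days + 1  # cover the morning after the last night
  dates <- cfg$start_date + seq_len(n_days_total) - 1

  # anchors: peaks at 14:00 on days 0..n_total, troughs at 06:00 on days 1..n_total+1
  mins <- rnorm(n_days_total + 1, cfg$ta_daily_min_mean, cfg$ta_daily_min_sd)
  maxs <- rnorm(n_days_total + 1, cfg$ta_daily_max_mean, cfg$ta_daily_max_sd)
  maxs <- pmax(maxs, mins[c(1, seq_len(n_days_total))])  # peak never below trough

  anchor_time <- c(rbind(at_hour(c(cfg$start_date - 1, dates), 14),
                         at_hour(c(dates, cfg$start_date + n_days_total), 6)))
  anchor_val <- c(rbind(maxs, mins))
  ord <- order(anchor_time)
  anchor_time <- anchor_time[ord]
  anchor_val <- anchor_val[ord]

  step <- cfg$sample_interval_min * 60
  grid <- seq(as.POSIXct(paste(cfg$start_date, "00:00:00"), tz = "UTC"),
              as.POSIXct(paste(dates[n_days_total], "23:59:59"), tz = "UTC"),
              by = step)
  seg <- findInterval(as.numeric(grid), as.numeric(anchor_time),
                      rightmost.closed = FALSE)
  seg <- pmin(pmax(seg, 1), length(anchor_time) - 1)
  ta <- half_cos_ramp(as.numeric(grid),
                      as.numeric(anchor_time)[seg], as.numeric(anchor_time)[seg + 1],
                      anchor_val[seg], anchor_val[seg + 1])
  if (cfg$ta_noise_sd > 0) {
    innov <- rnorm(length(grid), 0,
                   cfg$ta_noise_sd * sqrt(1 - cfg$ta_noise_ar^2))
    ta <- ta + as.numeric(stats::filter(innov, cfg$ta_noise_ar, method = "recursive"))
  }

  wind <- pmax(rnorm(n_days_total, cfg$wind_daily_max_mean, cfg$wind_daily_max_sd),
               cfg$wind_floor)

  out <- list(
    ta = tibble(time = grid, ta_c = ta),
    wind = tibble(date = dates, wind_max_kmh = wind)
  )
  study <- date_of(grid) <= cfg$start_date + cfg$n_days - 1
  attr(out, "ref_ta") <- mean(ta[study])
  class(out) <- "weather_series"
  out
}

#' Mean air temperature over a half-open time window
#'
#' Arithmetic mean of the samples with `start <= time < end`. The window must
#' be covered by at least `min_coverage` of its expected grid slots; otherwise
#' `NA` is returned with attribute `reason = "low_weather_coverage"`.
#'
#' @param weather a `weather_series` (or its `ta` tibble).
#' @param start,end POSIXct window bounds.
#' @param min_coverage minimum fraction of grid slots present (default 0.9).
#' @param interval_min grid spacing in minutes (default 10).
#' @return mean temperature in C, or `NA_real_`.
#' @export
ta_window_mean <- function(weather, start, end, min_coverage = 0.9,
                           interval_min = 10) {
  ta <- if (inherits(weather, "weather_series")) weather$ta else weather
  in_win <- ta$time >= start & ta$time < end
  vals <- ta$ta_c[in_win]
  vals <- vals[!is.na(vals)]
  expected <- as.numeric(difftime(end, start, units = "mins")) / interval_min
  if (length(vals) < min_coverage * expected) {
    return(structure(NA_real_, reason = "low_weather_coverage"))
  }
  mean(vals)
}
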