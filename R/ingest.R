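#' Circadian phase windows
#'
#' Clock-time windows (local study time, no daylight-saving shifts) used to
#' segment each bird's record: the nocturnal rest-phase spans `rest_start` to
#' `rest_end` the next morning; the diurnal active-phase spans `active_start`
#' to `active_end`; daily medians are computed on `median_start` to
#' `median_end`. All windows are half-open `[start, end)`. With the defaults
#' the 07:00-08:00 hour belongs to both the rest window and the active
#' window: nightly metrics use 17:00-08:00, daily medians 08:00-17:00, and
#' the lowest daily active-phase reading 07:00-17:00.
#'
#' @param rest_start,rest_end rest window bounds (hours; spans midnight).
#' @param active_start,active_end active window bounds (hours).
#' @param median_start,median_end daily-median window bounds (hours).
#' @return a `phase_windows` list.
#' @export
phase_windows <- function(rest_start = 17, rest_end = 8,
                          active_start = 7, active_end = 17,
                          median_start = 8, median_end = 17) {
  stopifnot(rest_start > rest_end,        # rest window must span midnight
            active_start < active_end,
            median_start >= active_start || median_start >= rest_end)
  structure(list(rest_start = rest_start, rest_end = rest_end,
                 active_start = active_start, active_end = active_end,
                 median_start = median_start, median_end = median_end),
            class = "phase_windows")
}

rest_window_hours <- function(windows) {
  (24 - windows$rest_start) + windows$rest_end
}

# Night date of each sample: samples at/after rest_start belong to that
# evening's night; samples before rest_end belong to the previous evening.
night_date_of <- function(time, windows) {
  h <- hour_of(time)
  d <- date_of(time)
  out <- as.Date(ifelse(h >= windows$rest_start, d,
                        ifelse(h < windows$rest_end, d - 1, NA)),
                 origin = "1970-01-01")
  out
}

#' Partition a bird's record into bird-nights
#'
#' One record per evening date with at least one observed rest-window sample:
#' the night's condition is the schedule condition of the *preceding daytime*
#' (the playback is an active-phase exposure), `missing_h` is counted against
#' the full rest window on the sampling grid, and nights missing more than
#' `max_missing_h` hours are excluded with reason `gap_gt_3h`. Nights on
#' dates without a schedule condition are dropped.
#'
#' @param ds a `torpor_dataset` ([read_dataset()] / [as_dataset()]).
#' @param windows a [phase_windows()].
#' @param max_missing_h exclusion threshold on missing rest-window hours
#'   (default 3).
#' @return tibble of bird-nights with inclusion flags (metrics unfilled).
#' @export
assign_nights <- function(ds, windows = phase_windows(), max_missing_h = 3) {
  step_h <- ds$config$sample_interval_min / 60
  full_h <- rest_window_hours(windows)
  ts <- ds$ts
  nd <- night_date_of(ts$time, windows)
  rest <- !is.na(nd)
  nights <- ts[rest, ] |>
    mutate(night_date = nd[rest]) |>
    group_by(.data$bird_id, .data$site, .data$night_date) |>
    summarise(n_samples = sum(!is.na(.data$ts_c)), .groups = "drop") |>
    mutate(missing_h = full_h - .data$n_samples * step_h)
  nights <- nights |>
    inner_join(ds$schedule |> select("site", "date", "condition"),
               by = c("site" = "site", "night_date" = "date")) |>
    filter(.data$n_samples >= 1) |>
    mutate(included = .data$missing_h <= max_missing_h,
           exclusion_reason = ifelse(.data$included, "none", "gap_gt_3h"))
  nights
}

#' Daily active-phase summaries
#'
#' Per bird-date: the median skin temperature over the median window when
#' strictly more than `min_median_samples` observations are present (else
#' missing), the lowest reading over the active window, and the observation
#' counts. The date's schedule condition is joined; dates without a schedule
#' entry are dropped.
#'
#' @param ds a `torpor_dataset`.
#' @param windows a [phase_windows()].
#' @param min_median_samples strict lower bound on the median sample count
#'   (default 20: a median needs > 20 points).
#' @return tibble of bird-days.
#' @export
daily_summaries <- function(ds, windows = phase_windows(),
                            min_median_samples = 20) {
  ts <- ds$ts
  h <- hour_of(ts$time)
  act <- h >= windows$active_start & h < windows$active_end
  med <- h >= windows$median_start & h < windows$median_end
  days <- ts[act, ] |>
    mutate(date = date_of(.data$time),
           in_med = med[act]) |>
    group_by(.data$bird_id, .data$site, .data$date) |>
    summarise(
      n_active_samples = sum(!is.na(.data$ts_c)),
      n_median_samples = sum(!is.na(.data$ts_c) & .data$in_med),
      median_active_ts = median(.data$ts_c[.data$in_med], na.rm = TRUE),
      lowest_active_ts = if (any(!is.na(.data$ts_c)))
        min(.data$ts_c, na.rm = TRUE) else NA_real_,
      .groups = "drop"
    ) |>
    mutate(median_active_ts = ifelse(.data$n_median_samples > min_median_samples,
                                     .data$median_active_ts, NA_real_))
  days |>
    inner_join(ds$schedule |> select("site", "date", "condition"),
               by = c("site", "date")) |>
    mutate(included = TRUE, exclusion_reason = "none")
}

#' Apply the carry-over exclusion
#'
#' Marks records whose date falls in the first `carryover_days` days of any
#' control block that immediately follows a treatment block as excluded
#' (reason `carryover_day`), limiting lingering treatment effects. A leading
#' control block is untouched. Records already excluded keep their original
#' reason.
#'
#' @param records a bird-night or bird-day tibble with `site` and a date
#'   column.
#' @param schedule the treatment schedule.
#' @param carryover_days days to drop at the start of each post-treatment
#'   control block (default 2).
#' @param date_col name of the date column (`"night_date"` for nights,
#'   `"date"` for days).
#' @return `records` with `included` / `exclusion_reason` updated.
#' @export
apply_carryover_exclusion <- function(records, schedule, carryover_days = 2,
                                      date_col = if ("night_date" %in% names(records))
                                        "night_date" else "date") {
  drop_tab <- bind_rows(lapply(split(schedule, schedule$site), function(s) {
    tibble(site = s$site[1],
           date = carryover_dates(s, carryover_days))
  }))
  if (nrow(drop_tab) == 0) return(records)
  hit <- paste(records$site, records[[date_col]]) %in%
    paste(drop_tab$site, drop_tab$date)
  records$exclusion_reason <- ifelse(hit & records$included,
                                     "carryover_day", records$exclusion_reason)
  records$included <- records$included & !hit
  records
}
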