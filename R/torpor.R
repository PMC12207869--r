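#' Estimate per-bird normothermic baselines and torpor thresholds
#'
#' A bird's resting normothermic skin temperature is the mean, over its
#' qualifying control days, of the lowest active-phase reading; its torpor
#' threshold is exactly 5 C (the `threshold_offset`) below that. Qualifying
#' days are included (non-carry-over) control days with an observed lowest
#' reading and at least `min_active_samples` active-phase observations.
#' Birds with no qualifying day are flagged unusable and dropped from the
#' night analyses downstream.
#'
#' @param days bird-day table from [daily_summaries()] (after
#'   [apply_carryover_exclusion()]).
#' @param threshold_offset threshold depth below the baseline, C (default 5).
#' @param min_active_samples minimum active-phase observations for a day to
#'   qualify (default 21, mirroring the strict > 20 median rule).
#' @return tibble: `bird_id`, `normothermic_ts`, `torpor_threshold`,
#'   `n_control_days_used`, `usable`.
#' @export
#' @examples
#' days <- tibble::tibble(bird_id = "b1", site = "S1",
#'                        date = as.Date("2022-06-16") + 0:2,
#'                        condition = factor("control",
#'                                           levels = c("control", "treatment")),
#'                        lowest_active_ts = c(37.0, 37.5, 37.4),
#'                        n_active_samples = 60, included = TRUE)
#' estimate_baseline(days)
estimate_baseline <- function(days, threshold_offset = 5,
                              min_active_samples = 21) {
  qual <- days |>
    filter(.data$condition == "control", .data$included,
           !is.na(.data$lowest_active_ts),
           .data$n_active_samples >= min_active_samples)
  out <- qual |>
    group_by(.data$bird_id) |>
    summarise(normothermic_ts = mean(.data$lowest_active_ts),
              n_control_days_used = n(), .groups = "drop") |>
    mutate(torpor_threshold = .data$normothermic_ts - threshold_offset,
           usable = TRUE)
  unusable <- setdiff(unique(days$bird_id), out$bird_id)
  if (length(unusable)) {
    message("no qualifying control day for bird(s): ",
            paste(unusable, collapse = ", "), "; dropped from night models")
    out <- bind_rows(out,
                     tibble(bird_id = unusable, normothermic_ts = NA_real_,
                            n_control_days_used = 0L,
                            torpor_threshold = NA_real_, usable = FALSE))
  }
  arrange(out, .data$bird_id)
}

#' Nightly torpor metrics for one set of rest-window samples
#'
#' `min_rest_ts` is the minimum observed sample; `torpor_duration_h` is the
#' sampled time strictly below the individual torpor threshold (number of
#' observed sub-threshold samples times the sampling interval), counting all
#' time below whether or not contiguous. A sample exactly at the threshold is
#' normothermic. Missing samples contribute no duration.
#'
#' @param ts_c numeric vector of rest-window samples (may contain `NA`).
#' @param threshold the bird's torpor threshold, C.
#' @param interval_min sampling interval, minutes.
#' @return list with `min_rest_ts` and `torpor_duration_h`.
#' @export
#' @examples
#' night_metrics(c(34, 31.9, 32.3, NA, 30.1), 32.3, 10)
night_metrics <- function(ts_c, threshold, interval_min) {
  obs <- ts_c[!is.na(ts_c)]
  list(
    min_rest_ts = if (length(obs)) min(obs) else NA_real_,
    torpor_duration_h = sum(obs < threshold) * interval_min / 60
  )
}

#' Fill nightly torpor metrics for all bird-nights
#'
#' Applies [night_metrics()] to every bird-night using each bird's torpor
#' threshold. Nights of unusable birds (no baseline) are excluded with
#' reason `no_baseline`.
#'
#' @param nights bird-night table from [assign_nights()].
#' @param ds the `torpor_dataset`.
#' @param baselines output of [estimate_baseline()].
#' @param windows a [phase_windows()].
#' @return `nights` with `min_rest_ts`, `torpor_duration_h`,
#'   `torpor_threshold` added.
#' @export
add_night_metrics <- function(nights, ds, baselines, windows = phase_windows()) {
  step <- ds$config$sample_interval_min
  ts <- ds$ts
  nd <- night_date_of(ts$time, windows)
  rest <- ts[!is.na(nd), ] |> mutate(night_date = nd[!is.na(nd)])
  rest <- left_join(rest,
                    baselines[, c("bird_id", "torpor_threshold", "usable")],
                    by = "bird_id")
  met <- rest |>
    group_by(.data$bird_id, .data$night_date) |>
    summarise(
      min_rest_ts = if (any(!is.na(.data$ts_c)))
        min(.data$ts_c, na.rm = TRUE) else NA_real_,
      torpor_duration_h = sum(.data$ts_c < .data$torpor_threshold,
                              na.rm = TRUE) * step / 60,
      .groups = "drop"
    )
  out <- nights |>
    left_join(met, by = c("bird_id", "night_date")) |>
    left_join(baselines[, c("bird_id", "torpor_threshold", "usable")],
              by = "bird_id")
  out$usable[is.na(out$usable)] <- FALSE
  out$exclusion_reason <- ifelse(!out$usable & out$included,
                                 "no_baseline", out$exclusion_reason)
  out$included <- out$included & out$usable
  out$torpor_duration_h[!out$usable] <- NA_real_
  select(out, -"usable")
}

#' Torpor bout onsets and offsets within one night
#'
#' Accessor returning the contiguous runs of observed sub-threshold samples
#' (a bout list). Total time below the threshold -- the quantity modeled --
#' is the sum of bout durations; bout segmentation itself is not used by the
#' models.
#'
#' @param time POSIXct sample times (regular grid).
#' @param ts_c samples (may contain `NA`).
#' @param threshold torpor threshold, C.
#' @param interval_min sampling interval, minutes.
#' @return tibble with `onset`, `offset`, `duration_h` per bout.
#' @export
torpor_bouts <- function(time, ts_c, threshold, interval_min) {
  below <- !is.na(ts_c) & ts_c < threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  tibble(onset = time[starts[keep]],
         offset = time[ends[keep]],
         duration_h = r$lengths[keep] * interval_min / 60)
}

#' Per-condition descriptive summary of nightly torpor
#'
#' Means, SDs and ranges of nightly minimum skin temperature and torpor
#' duration over included nights, by condition.
#'
#' @param nights bird-night table with metrics (see [add_night_metrics()]).
#' @return tibble, one row per condition.
#' @export
summarize_by_condition <- function(nights) {
  inc <- filter(nights, .data$included)
  out <- inc |>
    group_by(.data$condition) |>
    summarise(n_nights = n(),
              n_birds = n_distinct(.data$bird_id),
              min_ts_mean = mean(.data$min_rest_ts),
              min_ts_sd = sd(.data$min_rest_ts),
              min_ts_min = min(.data$min_rest_ts),
              min_ts_max = max(.data$min_rest_ts),
              duration_mean = mean(.data$torpor_duration_h),
              duration_sd = sd(.data$torpor_duration_h),
              duration_min = min(.data$torpor_duration_h),
              duration_max = max(.data$torpor_duration_h),
              .groups = "drop")
  empty <- setdiff(levels(nights$condition), as.character(out$condition))
  if (length(empty)) {
    warning("no included nights for condition(s): ",
            paste(empty, collapse = ", "))
  }
  out
}
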