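# Writing and re-reading the plain-text study bundle.

fmt_time <- function(t) format(t, "%Y-%m-%d %H:%M:%S", tz = "UTC")

# Full sampling grid of a scenario: 00:00 day 1 .. 08:00 of day n_days + 1.
full_grid <- function(cfg) {
  step <- cfg$sample_interval_min * 60
  seq(as.POSIXct(paste(cfg$start_date, "00:00:00"), tz = "UTC"),
      at_hour(cfg$start_date + cfg$n_days, 8) - step,
      by = step)
}

#' Write a simulated scenario as a plain-text file bundle
#'
#' Emits the artifacts a field study would produce: one receiver-logger CSV
#' per site (`timestamp`, `transmitter_id`, `pulse_interval_ms`, pulses
#' obtained by inverting each transmitter's true response curve plus a small
#' timing jitter), per-transmitter calibration tables, bird metadata, the
#' treatment schedule, the weather series, the scenario configuration
#' (YAML), and the ground-truth planted-parameter tables (`true_*.csv`,
#' synthetic ground truth that a real study would not have).
#'
#' Writing is deterministic: the same scenario produces byte-identical
#' bundles.
#'
#' @param scenario a [simulate_scenario()] result.
#' @param outdir directory to write into (created if needed).
#' @param jitter_ms SD of the pulse timing jitter added to logged pulses.
#' @return `outdir`, invisibly.
#' @export
emit_dataset <- function(scenario, outdir, jitter_ms = 0.02) {
  stopifnot(inherits(scenario, "torpor_scenario"))
  cfg <- scenario$config
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  wr <- function(x, name) {
    path <- file.path(outdir, name)
    ok <- try(readr::write_csv(x, path), silent = TRUE)
    if (inherits(ok, "try-error")) stop("failed to write ", path)
    path
  }

  set.seed((cfg$rng_seed %% 1000000L) * 2L + 101L)  # jitter stream, < 2^31

  cal_pts <- bind_rows(lapply(names(scenario$calibration), function(tx) {
    make_calibration_points(scenario$calibration[[tx]], tx)
  }))
  wr(cal_pts, "calibration_points.csv")

  obs <- scenario$ts[!is.na(scenario$ts$ts_c), ]
  obs <- left_join(obs, scenario$birds[, c("bird_id", "transmitter_id")], by = "bird_id")
  for (s in unique(scenario$birds$site)) {
    rows <- obs[obs$site == s, ]
    pulse <- vapply(seq_len(nrow(rows)), function(j) {
      true_temp_to_pulse(scenario$calibration[[rows$transmitter_id[j]]],
                         rows$ts_c[j])
    }, numeric(1))
    pulse <- pulse + rnorm(length(pulse), 0, jitter_ms)
    wr(tibble(timestamp = fmt_time(rows$time),
              transmitter_id = rows$transmitter_id,
              pulse_interval_ms = round(pulse, 4)),
       sprintf("logger_%s.csv", s))
  }

  wr(scenario$birds[, c("bird_id", "transmitter_id", "site", "sex", "body_mass_g")],
     "metadata.csv")
  wr(scenario$schedule |> mutate(condition = as.character(condition)), "schedule.csv")
  wr(scenario$weather$ta |> mutate(time = fmt_time(time)), "weather_ta.csv")
  wr(scenario$weather$wind, "weather_wind.csv")
  wr(scenario$truth |> mutate(condition = as.character(condition)), "true_effects.csv")
  wr(scenario$birds[, c("bird_id", "resting_ts", "plateau_ts")], "true_birds.csv")

  cfg_out <- unclass(cfg)
  cfg_out$start_date <- as.character(cfg_out$start_date)
  yaml::write_yaml(cfg_out, file.path(outdir, "scenario.yml"))
  invisible(outdir)
}

read_scenario_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$start_date <- as.Date(raw$start_date)
  do.call(scenario_config, raw)
}

#' Read a study bundle from disk
#'
#' Loads and validates the file bundle written by [emit_dataset()] (the same
#' schemas apply to real receiver-logger exports): fits each transmitter's
#' calibration curve, converts logged pulse intervals to skin temperatures,
#' collapses duplicate (bird, timestamp) rows to their median, drops rows
#' from transmitters without calibration or metadata (with a warning), and
#' regularises each bird's record onto the full sampling grid with `NA`
#' gaps.
#'
#' @param dir bundle directory.
#' @return an object of class `torpor_dataset`: list with `config`,
#'   `schedule`, `weather`, `birds`, `ts` (grid-complete per bird),
#'   `calibration` (fitted [fit_calibration()] curves) and `dropped_rows`
#'   count of unknown-transmitter rows.
#' @export
read_dataset <- function(dir) {
  need <- c("scenario.yml", "metadata.csv", "schedule.csv", "weather_ta.csv",
            "weather_wind.csv", "calibration_points.csv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) stop("bundle is missing file(s): ",
                            paste(file.path(dir, missing), collapse = ", "))
  cfg <- read_scenario_yaml(file.path(dir, "scenario.yml"))
  rd <- function(name, ...) readr::read_csv(file.path(dir, name),
                                            show_col_types = FALSE, ...)

  birds <- rd("metadata.csv") |>
    mutate(sex = factor(.data$sex, levels = c("F", "M")))
  schedule <- rd("schedule.csv") |>
    mutate(condition = factor(.data$condition, levels = c("control", "treatment")))
  ta <- rd("weather_ta.csv")
  ta$time <- as.POSIXct(ta$time, tz = "UTC")
  wind <- rd("weather_wind.csv")
  weather <- structure(list(ta = ta, wind = wind), class = "weather_series")
  study <- date_of(ta$time) <= cfg$start_date + cfg$n_days - 1
  attr(weather, "ref_ta") <- mean(ta$ta_c[study])

  cal_pts <- rd("calibration_points.csv")
  curves <- lapply(split(cal_pts, cal_pts$transmitter_id), function(pts) {
    fit_calibration(pts, pts$transmitter_id[1])
  })

  logger_files <- list.files(dir, pattern = "^logger_.*\\.csv$", full.names = TRUE)
  if (!length(logger_files)) stop("bundle has no logger_*.csv files in ", dir)
  logs <- bind_rows(lapply(logger_files, function(f) {
    x <- readr::read_csv(f, show_col_types = FALSE)
    bad <- is.na(as.POSIXct(x$timestamp, tz = "UTC"))
    if (any(bad)) stop("unparseable timestamp in ", f, " at data line ",
                       which(bad)[1])
    x$timestamp <- as.POSIXct(x$timestamp, tz = "UTC")
    x
  }))

  known <- logs$transmitter_id %in% birds$transmitter_id
  dropped <- sum(!known)
  if (dropped > 0) {
    warning(dropped, " logger row(s) from unknown transmitter(s) dropped: ",
            paste(unique(logs$transmitter_id[!known]), collapse = ", "))
    logs <- logs[known, ]
  }
  uncalibrated <- setdiff(unique(logs$transmitter_id), names(curves))
  if (length(uncalibrated)) {
    stop("no calibration table for transmitter(s): ",
         paste(uncalibrated, collapse = ", "))
  }

  logs$ts_c <- NA_real_
  for (tx in unique(logs$transmitter_id)) {
    idx <- logs$transmitter_id == tx
    logs$ts_c[idx] <- as.numeric(pulse_to_temperature(curves[[tx]],
                                                      logs$pulse_interval_ms[idx]))
  }

  logs <- left_join(logs, birds[, c("bird_id", "transmitter_id", "site")],
                    by = "transmitter_id")
  # duplicate (bird, timestamp) rows collapse to their median reading
  obs <- logs |>
    group_by(.data$bird_id, .data$site, .data$timestamp) |>
    summarise(ts_c = median(.data$ts_c, na.rm = TRUE), .groups = "drop") |>
    rename(time = "timestamp")

  grid <- full_grid(cfg)
  ts <- tidyr::expand_grid(bird_id = birds$bird_id, time = grid) |>
    left_join(birds[, c("bird_id", "site")], by = "bird_id") |>
    left_join(obs[, c("bird_id", "time", "ts_c")], by = c("bird_id", "time")) |>
    select("bird_id", "site", "time", "ts_c") |>
    arrange(.data$bird_id, .data$time)

  structure(list(config = cfg, schedule = schedule, weather = weather,
                 birds = birds, ts = ts, calibration = curves,
                 dropped_rows = dropped),
            class = "torpor_dataset")
}

#' Use a simulated scenario directly as an analysis dataset
#'
#' Skips the file round-trip: the observed (noisy, gapped) series feeds the
#' pipeline as-is, without the pulse-interval encoding step.
#'
#' @param scenario a [simulate_scenario()] result.
#' @return a `torpor_dataset`.
#' @export
as_dataset <- function(scenario) {
  stopifnot(inherits(scenario, "torpor_scenario"))
  grid <- full_grid(scenario$config)
  ts <- tidyr::expand_grid(bird_id = scenario$birds$bird_id, time = grid) |>
    left_join(scenario$birds[, c("bird_id", "site")], by = "bird_id") |>
    left_join(scenario$ts[, c("bird_id", "time", "ts_c")], by = c("bird_id", "time")) |>
    select("bird_id", "site", "time", "ts_c") |>
    arrange(.data$bird_id, .data$time)
  structure(list(config = scenario$config, schedule = scenario$schedule,
                 weather = scenario$weather, birds = scenario$birds,
                 ts = ts, calibration = NULL, dropped_rows = 0L),
            class = "torpor_dataset")
}
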