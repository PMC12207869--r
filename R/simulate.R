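#' Simulate a complete synthetic study
#'
#' Generates schedule, weather, bird metadata, per-bird skin-temperature
#' series (with sensor noise and out-of-range gaps), true transmitter
#' calibration curves, and the ground-truth table of planted per-night torpor
#' parameters. All randomness is governed by `cfg$rng_seed`: identical
#' configurations produce identical scenarios.
#'
#' Per-bird physiology is drawn once per bird: the active plateau from
#' `N(active_plateau_mean, active_plateau_sd_between_birds)` and the resting
#' normothermic level as plateau minus a truncated-normal plateau-rest gap,
#' so that the resting level has exactly the configured mean and
#' between-bird SD while always sitting at least 1 C below the plateau.
#'
#' The series covers 00:00 of day 1 through 08:00 of day `n_days + 1`, so
#' every study night (17:00-08:00) is fully sampled.
#'
#' @param cfg a [scenario_config()].
#' @return an object of class `torpor_scenario`: list with `config`,
#'   `schedule`, `weather`, `birds` (metadata + true physiology), `ts`
#'   (tibble `bird_id`, `site`, `time`, `ts_true`, `ts_c`), `calibration`
#'   (true per-transmitter curves) and `truth` (planted bird-night table).
#' @export
#' @examples
#' sc <- simulate_scenario(scenario_config(n_days = 5, rng_seed = 3))
#' nrow(sc$truth)
simulate_scenario <- function(cfg) {
  validate_scenario(cfg)
  set.seed(cfg$rng_seed)

  schedule <- make_schedule(cfg)
  weather <- simulate_weather(cfg, seed = NULL)

  n_birds <- cfg$n_sites * cfg$birds_per_site
  sites <- site_ids(cfg$n_sites)
  f_per_site <- diff(round(seq(0, cfg$n_females, length.out = cfg$n_sites + 1)))
  sex <- unlist(lapply(seq_len(cfg$n_sites), function(i) {
    c(rep("F", f_per_site[i]), rep("M", cfg$birds_per_site - f_per_site[i]))
  }))
  plateau <- rnorm(n_birds, cfg$active_plateau_mean, cfg$active_plateau_sd_between_birds)
  gap_mean <- cfg$active_plateau_mean - cfg$resting_normothermic_mean
  gap_sd <- sqrt(max(cfg$resting_normothermic_sd_between_birds^2 -
                       cfg$active_plateau_sd_between_birds^2, 1e-4))
  gap <- rtrunc_norm(n_birds, gap_mean, gap_sd, lower = 1)
  birds <- tibble(
    bird_id = sprintf("B%02d", seq_len(n_birds)),
    transmitter_id = sprintf("tx%02d", seq_len(n_birds)),
    site = rep(sites, each = cfg$birds_per_site),
    sex = factor(sex, levels = c("F", "M")),
    body_mass_g = round(rnorm(n_birds, 9.0, 0.6), 1),
    resting_ts = plateau - gap,
    plateau_ts = plateau
  )

  step_h <- cfg$sample_interval_min / 60
  dates <- cfg$start_date + seq_len(cfg$n_days) - 1
  ts_list <- vector("list", n_birds)
  truth_list <- vector("list", n_birds)
  for (i in seq_len(n_birds)) {
    bird <- birds[i, ]
    sched_i <- schedule[schedule$site == bird$site, ]
    day_out <- lapply(seq_along(dates), function(d) {
      simulate_bird_trace(bird, dates[d],
                          sched_i$condition[sched_i$date == dates[d]],
                          weather, cfg)
    })
    samples <- bind_rows(lapply(day_out, `[[`, "samples"))

    # lead-in (00:00-07:00 day 1) at the resting level, and the final morning
    # rewarming arc (07:00-08:00 of day n_days + 1)
    pre_h <- seq(0, 7 - step_h, by = step_h)
    pre <- tibble(time = at_hour(dates[1], pre_h),
                  ts_true = rep(bird$resting_ts, length(pre_h)))
    post_h <- seq(7, 8 - step_h, by = step_h)
    post <- tibble(time = at_hour(dates[cfg$n_days] + 1, post_h),
                   ts_true = quarter_sin_rise(post_h, 7, 8, bird$resting_ts,
                                           bird$plateau_ts))
    add_obs <- function(df) {
      df$ts_c <- pmin(pmax(df$ts_true +
                             rnorm(nrow(df), 0, cfg$measurement_noise_sd), 15), 45)
      df$ts_c[runif(nrow(df)) < cfg$nighttime_missing_prob] <- NA_real_
      df
    }
    samples <- bind_rows(add_obs(pre), samples, add_obs(post))
    samples$bird_id <- bird$bird_id
    samples$site <- bird$site
    ts_list[[i]] <- samples
    truth_list[[i]] <- bind_rows(lapply(day_out, `[[`, "truth"))
  }

  calibration <- lapply(seq_len(n_birds), function(i) make_true_curve())
  names(calibration) <- birds$transmitter_id

  structure(list(
    config = cfg,
    schedule = schedule,
    weather = weather,
    birds = birds,
    ts = bind_rows(ts_list) |> select("bird_id", "site", "time", "ts_true", "ts_c"),
    calibration = calibration,
    truth = bind_rows(truth_list),
    ref_ta = attr(weather, "ref_ta")
  ), class = "torpor_scenario")
}

#' @export
print.torpor_scenario <- function(x, ...) {
  cat(sprintf("<torpor_scenario> %d birds, %d days, %d samples (%.1f%% missing)\n",
              nrow(x$birds), x$config$n_days, nrow(x$ts),
              100 * mean(is.na(x$ts$ts_c))))
  invisible(x)
}
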