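#' Scenario configuration for the synthetic telemetry generator
#'
#' Defines the study conditions emulated by the generator: the two-site
#' alternating-block playback design, winter weather, per-bird thermal
#' physiology, and the planted treatment and air-temperature effects on
#' nightly torpor depth and duration. The defaults describe a winter field
#' experiment on a small heterothermic passerine: 2 sites x 8 birds
#' (6 females, 10 males in total), 15 days of alternating 5-day
#' control/treatment blocks in opposing sequence between sites, 10-min
#' sampling, and daytime out-of-range gaps.
#'
#' Planted effects are expressed on the natural scales of the response
#' variables: degrees Celsius for skin-temperature quantities, hours for
#' torpor duration, and per-degree slopes for air-temperature terms. Slope
#' terms act on the deviation of the relevant air-temperature average from the
#' scenario's grand-mean air temperature.
#'
#' @param n_sites number of sites (social groups). Each site gets its own
#'   receiver logger and an opposing treatment sequence.
#' @param birds_per_site birds carrying transmitters at each site.
#' @param n_females,n_males sex totals across all birds.
#' @param start_date first study date (`Date` or `"YYYY-MM-DD"`).
#' @param n_days study length in days; must be a positive multiple of
#'   `block_length_days`.
#' @param block_length_days length of each control/treatment block.
#' @param sample_interval_min telemetry sampling interval, minutes.
#' @param active_plateau_mean,active_plateau_sd_between_birds mean and
#'   between-bird SD of the daytime active-phase skin-temperature plateau (C).
#' @param ta_slope_daytime planted effect of active-phase mean air temperature
#'   on the daytime plateau (C per C).
#' @param treatment_effect_daytime planted daytime treatment effect on the
#'   plateau (C; negative = slight reduction on playback days).
#' @param resting_normothermic_mean,resting_normothermic_sd_between_birds mean
#'   and between-bird SD of resting normothermic skin temperature (C). Each
#'   bird's torpor threshold is its resting level minus 5 C.
#' @param control_min_ts_mean,control_min_ts_sd mean and night-to-night SD of
#'   the planted nightly minimum skin temperature on control nights (C).
#' @param treatment_effect_min_ts planted treatment effect on the nightly
#'   minimum (C; negative = deeper torpor after playback days).
#' @param ta_slope_min_ts planted effect of 24-h mean air temperature on the
#'   nightly minimum (C per C, positive: warmer nights -> shallower torpor).
#' @param control_torpor_duration_mean,control_torpor_duration_sd mean and SD
#'   of planted nightly torpor duration on control nights (h). Draws are
#'   censored to \[0, 12\] h.
#' @param treatment_effect_duration planted treatment effect on duration (h).
#' @param ta_slope_duration planted effect of 24-h mean air temperature on
#'   duration (h per C, negative: warmer nights -> shorter bouts).
#' @param measurement_noise_sd Gaussian sensor noise SD on each sample (C).
#' @param daytime_missing_prob,nighttime_missing_prob independent per-sample
#'   deletion probabilities during 08:00-17:00 vs. the rest of the day,
#'   emulating out-of-range foraging gaps.
#' @param ta_daily_min_mean,ta_daily_min_sd distribution of daily minimum air
#'   temperature (C), trough near 06:00.
#' @param ta_daily_max_mean,ta_daily_max_sd distribution of daily maximum air
#'   temperature (C), peak near 14:00.
#' @param ta_noise_sd,ta_noise_ar SD and lag-1 autocorrelation of the small
#'   AR(1) noise added to the air-temperature sinusoid.
#' @param wind_daily_max_mean,wind_daily_max_sd distribution of daily maximum
#'   wind speed (km/h).
#' @param wind_floor lower clamp on daily maximum wind speed (km/h).
#' @param rng_seed integer seed controlling every random draw of the scenario.
#'
#' @return an object of class `scenario_config` (a validated named list).
#' @seealso [scenario_preset()], [simulate_scenario()]
#' @export
#' @examples
#' cfg <- scenario_config(n_days = 5, rng_seed = 42)
#' cfg$block_length_days
scenario_config <- function(n_sites = 2,
                            birds_per_site = 8,
                            n_females = 6,
                            n_males = 10,
                            start_date = as.Date("2022-06-16"),
                            n_days = 15,
                            block_length_days = 5,
                            sample_interval_min = 10,
                            active_plateau_mean = 39.6,
                            active_plateau_sd_between_birds = 1.0,
                            ta_slope_daytime = 0.17,
                            treatment_effect_daytime = -0.2,
                            resting_normothermic_mean = 37.3,
                            resting_normothermic_sd_between_birds = 1.2,
                            control_min_ts_mean = 30.0,
                            control_min_ts_sd = 1.5,
                            treatment_effect_min_ts = -1.25,
                            ta_slope_min_ts = 0.15,
                            control_torpor_duration_mean = 3.8,
                            control_torpor_duration_sd = 2.3,
                            treatment_effect_duration = 2.1,
                            ta_slope_duration = -0.15,
                            measurement_noise_sd = 0.3,
                            daytime_missing_prob = 0.25,
                            nighttime_missing_prob = 0.02,
                            ta_daily_min_mean = 2.5,
                            ta_daily_min_sd = 3.1,
                            ta_daily_max_mean = 17.2,
                            ta_daily_max_sd = 2.4,
                            ta_noise_sd = 0.3,
                            ta_noise_ar = 0.8,
                            wind_daily_max_mean = 32.2,
                            wind_daily_max_sd = 15.5,
                            wind_floor = 11,
                            rng_seed = 1L) {
  cfg <- as.list(environment())
  cfg$start_date <- as.Date(start_date)
  class(cfg) <- "scenario_config"
  validate_scenario(cfg)
  cfg
}

#' Named scenario presets
#'
#' `"fairywren-winter"` is the reference scenario: the generator defaults of
#' [scenario_config()], i.e. the winter field-study conditions with the
#' planted treatment effects on torpor depth (-1.25 C) and duration (+2.1 h).
#'
#' @param name preset name.
#' @param ... overrides passed to [scenario_config()] (e.g. `rng_seed`).
#' @return a `scenario_config`.
#' @export
scenario_preset <- function(name = "fairywren-winter", ...) {
  switch(name,
    "fairywren-winter" = scenario_config(...),
    stop("unknown scenario preset: ", name)
  )
}

#' Validate a scenario configuration
#'
#' Checks the structural invariants: the block length divides the study length,
#' probabilities lie in \[0, 1\], SDs are non-negative, and the sampling
#' interval is a positive divisor of 60 minutes.
#'
#' @param cfg a `scenario_config`.
#' @return `cfg`, invisibly; errors on violation.
#' @export
validate_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (cfg$n_days <= 0 || cfg$block_length_days <= 0 ||
      cfg$n_days %% cfg$block_length_days != 0) {
    stop("n_days (", cfg$n_days, ") must be a positive multiple of ",
         "block_length_days (", cfg$block_length_days, ")")
  }
  probs <- c(cfg$daytime_missing_prob, cfg$nighttime_missing_prob)
  if (any(probs < 0 | probs > 1)) stop("missingness probabilities must be in [0, 1]")
  sds <- c(cfg$active_plateau_sd_between_birds, cfg$resting_normothermic_sd_between_birds,
           cfg$control_min_ts_sd, cfg$control_torpor_duration_sd,
           cfg$measurement_noise_sd, cfg$ta_daily_min_sd, cfg$ta_daily_max_sd,
           cfg$ta_noise_sd, cfg$wind_daily_max_sd)
  if (any(sds < 0)) stop("all SD fields must be >= 0")
  if (cfg$sample_interval_min <= 0 || 60 %% cfg$sample_interval_min != 0) {
    stop("sample_interval_min must be a positive divisor of 60")
  }
  if (cfg$n_females + cfg$n_males != cfg$n_sites * cfg$birds_per_site) {
    stop("n_females + n_males must equal n_sites * birds_per_site")
  }
  invisible(cfg)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat(sprintf("  %d sites x %d birds, %d days (%d-day blocks), %d-min sampling\n",
              x$n_sites, x$birds_per_site, x$n_days, x$block_length_days,
              x$sample_interval_min))
  cat(sprintf("  planted effects: min Ts %+0.2f C, duration %+0.2f h, daytime %+0.2f C\n",
              x$treatment_effect_min_ts, x$treatment_effect_duration,
              x$treatment_effect_daytime))
  cat(sprintf("  seed %d\n", x$rng_seed))
  invisible(x)
}
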