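#' Simulate one bird-day and its following night
#'
#' Generates the skin-temperature trace on the sampling grid for the window
#' from 07:00 of `date` to 07:00 of the next day: morning rewarming arc from
#' the resting normothermic level `R` to the day's active plateau, the
#' plateau itself, the evening cooling arc, a planted torpor bout (time below
#' `R - 5` C equals the planted duration, nightly minimum equals the planted
#' minimum), and the pre-dawn rewarming arc back to `R`. Gaussian sensor
#' noise is added and samples are deleted independently with the daytime
#' missingness probability during 08:00-17:00 and the nighttime probability
#' otherwise.
#'
#' The planted nightly minimum and duration are drawn from the condition- and
#' air-temperature-adjusted distributions of the scenario unless supplied via
#' `planted`. Durations are censored to \[0, 12\] h (flagged `truncated`), and
#' the two draws are reconciled so they are physically consistent: a night
#' with zero planted duration draws its minimum at or above the torpor
#' threshold, a night with positive duration below it.
#'
#' @param bird one row (list or single-row data frame) with `bird_id`,
#'   `resting_ts` and `plateau_ts`.
#' @param date the day whose active phase precedes the night (`Date`).
#' @param condition `"control"` or `"treatment"` (that day's condition).
#' @param weather a [simulate_weather()] object covering the window.
#' @param cfg the [scenario_config()].
#' @param planted optional list with `min_ts` and `duration_h` to plant
#'   directly (no random draw).
#' @return list with `samples` (tibble `time`, `ts_true` noiseless,
#'   `ts_c` observed with `NA` gaps) and `truth` (one-row tibble of planted
#'   values).
#' @export
simulate_bird_trace <- function(bird, date, condition, weather, cfg,
                                planted = NULL) {
  bird <- as.list(bird)
  date <- as.Date(date)
  treat <- as.character(condition) == "treatment"
  step_h <- cfg$sample_interval_min / 60
  hours <- seq(7, 31 - step_h, by = step_h)  # 07:00 today .. 06:xx tomorrow
  times <- at_hour(date, hours)

  ref <- attr(weather, "ref_ta")
  ta_active <- ta_window_mean(weather, at_hour(date, 7), at_hour(date, 17),
                              interval_min = cfg$sample_interval_min)
  ta_night <- ta_window_mean(weather, at_hour(date, 7), at_hour(date + 1, 7),
                             interval_min = cfg$sample_interval_min)

  R <- bird$resting_ts
  theta <- R - 5
  plateau <- bird$plateau_ts + cfg$ta_slope_daytime * (ta_active - ref) +
    cfg$treatment_effect_daytime * treat

  if (is.null(planted)) {
    mu_d <- cfg$control_torpor_duration_mean +
      cfg$treatment_effect_duration * treat +
      cfg$ta_slope_duration * (ta_night - ref)
    d_raw <- rnorm(1, mu_d, cfg$control_torpor_duration_sd)
    D <- min(max(d_raw, 0), 12)
    truncated <- d_raw < 0 || d_raw > 12
    mu_m <- cfg$control_min_ts_mean +
      cfg$treatment_effect_min_ts * treat +
      cfg$ta_slope_min_ts * (ta_night - ref)
    m_raw <- m <- rtrunc_norm(1, mu_m, cfg$control_min_ts_sd, lower = 20, upper = R)
    # The two draws are independent, so a small fraction of nights is
    # physically contradictory (positive duration with a minimum at or above
    # the threshold, or vice versa). Reflect the minimum about the threshold
    # for those nights: the reflection is mean-preserving to first order, so
    # the configured condition means survive the reconciliation.
    if (D > 0 && m >= theta) m <- max(2 * theta - m - 0.01, 20)
    if (D == 0 && m < theta) m <- min(2 * theta - m, R)
  } else {
    m_raw <- m <- planted$min_ts
    d_raw <- planted$duration_h
    D <- min(max(planted$duration_h, 0), 12)
    truncated <- planted$duration_h > 12 || planted$duration_h < 0
  }

  y <- noiseless_day_night(hours, step_h, R, plateau, theta, m, D)

  noise <- rnorm(length(y), 0, cfg$measurement_noise_sd)
  obs <- pmin(pmax(y + noise, 15), 45)  # physiological guard band
  p_miss <- ifelse(hours >= 8 & hours < 17,
                   cfg$daytime_missing_prob, cfg$nighttime_missing_prob)
  obs[runif(length(obs)) < p_miss] <- NA_real_

  list(
    samples = tibble(time = times, ts_true = y, ts_c = obs),
    truth = tibble(bird_id = bird$bird_id,
                   night_date = date,
                   condition = factor(as.character(condition),
                                      levels = c("control", "treatment")),
                   planted_min_ts = m,
                   planted_duration_h = D,
                   raw_min_ts = m_raw,
                   raw_duration_h = d_raw,
                   truncated = truncated,
                   ta_night = ta_night,
                   ta_active = ta_active,
                   torpor_threshold = theta)
  )
}

# Piecewise noiseless trace over hours in [7, 31): quarter-sine morning
# rewarming (07:00-08:00), flat plateau (08:00-17:00), quarter-cosine evening
# cooling, linear V torpor bout (minimum at a grid-aligned point, time
# strictly below theta equal to D), quarter-sine pre-dawn rewarming reaching
# R at 07:00. Arc shapes at the threshold, at the trough and at the 07:00
# resting-level anchor have non-zero slope so that threshold crossings, the
# nightly minimum and the daily lowest active reading are robust order
# statistics under sensor noise.
noiseless_day_night <- function(hours, step_h, R, plateau, theta, m, D) {
  y <- numeric(length(hours))
  morn <- hours < 8
  y[morn] <- quarter_sin_rise(hours[morn], 7, 8, R, plateau)
  day <- hours >= 8 & hours < 17
  y[day] <- plateau

  night <- hours >= 17
  h <- hours[night]
  if (D > 0 && m < theta) {
    ctr <- round((30 - D / 2) / step_h) * step_h  # snap trough to the grid
    b0 <- ctr - D / 2
    b1 <- ctr + D / 2
    # Bout interior: brief steep drops (6 min) just inside each threshold
    # crossing and just above the minimum, joined linearly. Fast crossings
    # keep the time below threshold identifiable under sensor noise (a slow
    # drift near the threshold would let symmetric noise eat the bout), and
    # the terminal plunge leaves at most one sample near the minimum so the
    # observed nightly minimum tracks the planted one.
    depth <- theta - m
    tau <- 0.1
    if (D / 2 > 2.5 * tau && depth > 0.1) {
      de <- min(0.45, 0.4 * depth)  # drop inside each crossing
      db <- min(0.30, 0.4 * depth)  # terminal plunge to the minimum
      down <- approx(c(b0, b0 + tau, ctr - tau, ctr),
                     c(theta, theta - de, m + db, m), xout = h)$y
      up <- approx(c(ctr, ctr + tau, b1 - tau, b1),
                   c(m, m + db, theta - de, theta), xout = h)$y
    } else {
      down <- theta + (m - theta) * (h - b0) / max(ctr - b0, 1e-9)
      up <- m + (theta - m) * (h - ctr) / max(b1 - ctr, 1e-9)
    }
    yn <- ifelse(h < b0, quarter_cos_fall(h, 17, b0, plateau, theta),
          ifelse(h < ctr, down,
          ifelse(h < b1, up,
                 quarter_sin_rise(h, b1, 31, theta, R))))
  } else {
    ctr <- round(25 / step_h) * step_h  # shallow night, minimum near 01:00
    yn <- ifelse(h < ctr, quarter_cos_fall(h, 17, ctr, plateau, m),
                 quarter_sin_rise(h, ctr, 31, m, R))
  }
  y[night] <- yn
  y
}
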