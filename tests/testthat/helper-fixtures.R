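# Shared fixtures for the test suite. Everything is generated in code; the
# small configuration keeps per-test runtime low, while the full default
# scenario is reserved for the acceptance suite.

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

small_config <- function(seed = 1, ...) {
  scenario_config(n_days = 10, rng_seed = seed, ...)
}

# Deterministic clean scenario: no noise, no gaps. Construction identities
# hold exactly on these data.
clean_config <- function(seed = 1, ...) {
  scenario_config(rng_seed = seed, measurement_noise_sd = 0,
                  daytime_missing_prob = 0, nighttime_missing_prob = 0, ...)
}

# Memoised default-scenario analysis used by several test files.
.fixture_env <- new.env(parent = emptyenv())
default_analysis <- function(seed = 7) {
  key <- paste0("run", seed)
  if (is.null(.fixture_env[[key]])) {
    sc <- simulate_scenario(scenario_config(rng_seed = seed))
    .fixture_env[[key]] <- list(sc = sc,
                                res = quiet(analyze_dataset(as_dataset(sc))))
  }
  .fixture_env[[key]]
}

# Exact calibration points from a known polynomial relation.
linear_cal_points <- function(slope = -0.01, intercept = 40,
                              pulses = seq(600, 1400, by = 100)) {
  data.frame(pulse_interval_ms = pulses,
             temperature_c = intercept + slope * pulses)
}

# A small balanced bird-night table with a known treatment effect, for
# model-level tests that do not need the full generator.
toy_night_table <- function(n_birds = 10, n_nights = 12, effect = -1.2,
                            bird_sd = 0.8, resid_sd = 1.0, seed = 99) {
  set.seed(seed)
  grid <- expand.grid(bird_id = sprintf("b%02d", seq_len(n_birds)),
                      night = seq_len(n_nights))
  grid$condition <- factor(ifelse(grid$night %% 2 == 0, "treatment", "control"),
                           levels = c("control", "treatment"))
  grid$ta <- rnorm(nrow(grid), 8, 2)
  grid$wind <- rnorm(nrow(grid), 32, 10)
  bird_int <- rnorm(n_birds, 0, bird_sd)
  grid$mass <- rep(round(rnorm(n_birds, 9, 0.5), 1), times = n_nights)
  grid$sex <- factor(rep(rep(c("F", "M"), length.out = n_birds), times = n_nights),
                     levels = c("F", "M"))
  grid$min_rest_ts <- 30 + effect * (grid$condition == "treatment") +
    0.15 * (grid$ta - 8) + bird_int[as.integer(factor(grid$bird_id))] +
    rnorm(nrow(grid), 0, resid_sd)
  tibble::as_tibble(grid)
}
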