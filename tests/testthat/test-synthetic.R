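test_that("planted values are reproduced exactly on a noiseless trace", {
  cfg <- clean_config()
  w <- simulate_weather(cfg)
  bird <- list(bird_id = "b1", resting_ts = 37.3, plateau_ts = 39.6)
  set.seed(1)
  out <- simulate_bird_trace(bird, cfg$start_date + 3, "treatment", w, cfg,
                             planted = list(min_ts = 28.0, duration_h = 5))
  thr <- 37.3 - 5
  night <- out$samples$ts_true[torportel:::hour_of(out$samples$time) >= 17 |
                               torportel:::hour_of(out$samples$time) < 7]
  expect_equal(min(night), 28.0)
  below_h <- sum(night < thr) * cfg$sample_interval_min / 60
  expect_lt(abs(below_h - 5), cfg$sample_interval_min / 60 + 1e-9)
  # lowest active-phase sample equals the resting normothermic level exactly
  act <- out$samples$ts_true[torportel:::hour_of(out$samples$time) >= 7 &
                             torportel:::hour_of(out$samples$time) < 17]
  expect_equal(min(act), 37.3)
})

test_that("planted control-night minima and durations match their settings", {
  truth <- dplyr::bind_rows(lapply(1:20, function(i) {
    simulate_scenario(scenario_config(rng_seed = 1000 + i))$truth
  }))
  ctrl <- truth[truth$condition == "control", ]
  trt <- truth[truth$condition == "treatment", ]
  expect_lt(abs(mean(ctrl$planted_min_ts) - 30.0), 0.2)
  expect_lt(abs(mean(trt$planted_min_ts) - 28.75), 0.2)
  expect_lt(abs(mean(ctrl$planted_duration_h) - 3.85), 0.25)
  expect_lt(abs(mean(trt$planted_duration_h) - 5.92), 0.25)
})

test_that("identical seeds reproduce identical scenarios", {
  a <- simulate_scenario(small_config(seed = 21))
  b <- simulate_scenario(small_config(seed = 21))
  expect_identical(a$ts, b$ts)
  expect_identical(a$truth, b$truth)
  c <- simulate_scenario(small_config(seed = 22))
  expect_false(identical(a$ts$ts_c, c$ts$ts_c))
})

test_that("generated temperatures stay inside the physiological guard band", {
  sc <- simulate_scenario(scenario_config(rng_seed = 31,
                                          measurement_noise_sd = 2))
  expect_true(all(sc$ts$ts_c >= 15 & sc$ts$ts_c <= 45, na.rm = TRUE))
})

test_that("planted minima are physically consistent with durations", {
  sc <- simulate_scenario(scenario_config(rng_seed = 32))
  tr <- dplyr::left_join(sc$truth,
                         sc$birds[, c("bird_id", "resting_ts")], by = "bird_id")
  expect_true(all(tr$planted_min_ts <= tr$resting_ts + 1e-9))
  pos <- tr$planted_duration_h > 0
  expect_true(all(tr$planted_min_ts[pos] < tr$torpor_threshold[pos]))
  expect_true(all(tr$planted_min_ts[!pos] >= tr$torpor_threshold[!pos]))
  expect_true(all(tr$planted_duration_h >= 0 & tr$planted_duration_h <= 12))
})

test_that("over-long duration draws are censored and flagged", {
  cfg <- clean_config()
  w <- simulate_weather(cfg)
  bird <- list(bird_id = "b1", resting_ts = 37.3, plateau_ts = 39.6)
  set.seed(2)
  out <- simulate_bird_trace(bird, cfg$start_date, "control", w, cfg,
                             planted = list(min_ts = 28, duration_h = 14))
  expect_true(out$truth$truncated)
  expect_equal(out$truth$planted_duration_h, 12)
})

test_that("between-bird physiology has the configured mean and spread", {
  birds <- dplyr::bind_rows(lapply(1:15, function(i) {
    simulate_scenario(scenario_config(rng_seed = 1100 + i))$birds
  }))
  expect_lt(abs(mean(birds$resting_ts) - 37.3), 0.25)
  expect_lt(abs(sd(birds$resting_ts) - 1.2), 0.25)
  expect_lt(abs(mean(birds$plateau_ts) - 39.6), 0.25)
  expect_true(all(birds$plateau_ts - birds$resting_ts >= 1))
  expect_equal(sum(birds$sex == "F"), 15 * 6)
})
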