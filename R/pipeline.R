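#' Pipeline run configuration
#'
#' Bundles every tunable of a full analysis run: the data source (a scenario
#' to simulate or a bundle directory), phase windows, the torpor-threshold
#' offset, the exclusion parameters, model options and seeds. The
#' configuration is serialised into the output directory so a run is
#' reproducible from its artifacts alone.
#'
#' @param scenario a [scenario_config()] to simulate, or `NULL` when reading
#'   from `data_dir`.
#' @param data_dir directory with a study bundle ([read_dataset()] layout),
#'   or `NULL` to simulate `scenario` in memory.
#' @param out_dir optional output directory for run artifacts.
#' @param windows a [phase_windows()].
#' @param threshold_offset torpor threshold depth below baseline, C.
#' @param max_missing_h nightly gap exclusion threshold, h.
#' @param carryover_days control days dropped after each treatment block.
#' @param min_median_samples strict minimum sample count for daily medians.
#' @param min_active_samples minimum active samples for baseline days.
#' @param df_method degrees-of-freedom approximation for model p-values.
#' @param n_boot bootstrap replicates for prediction intervals (0 = skip).
#' @param boot_seed seed for the bootstrap stream.
#' @param make_plots write trace/distribution figures when `out_dir` is set.
#' @return a `run_config` list.
#' @export
run_config <- function(scenario = scenario_preset(), data_dir = NULL,
                       out_dir = NULL, windows = phase_windows(),
                       threshold_offset = 5, max_missing_h = 3,
                       carryover_days = 2, min_median_samples = 20,
                       min_active_samples = 21,
                       df_method = c("satterthwaite", "residual"),
                       n_boot = 0, boot_seed = 1, make_plots = FALSE) {
  structure(list(scenario = scenario, data_dir = data_dir, out_dir = out_dir,
                 windows = windows, threshold_offset = threshold_offset,
                 max_missing_h = max_missing_h, carryover_days = carryover_days,
                 min_median_samples = min_median_samples,
                 min_active_samples = min_active_samples,
                 df_method = match.arg(df_method),
                 n_boot = n_boot, boot_seed = boot_seed,
                 make_plots = make_plots),
            class = "run_config")
}

#' Analyse a loaded dataset
#'
#' The core pipeline: daily summaries, bird-night partitioning, carry-over
#' and gap exclusions, per-bird baselines and torpor thresholds, nightly
#' depth/duration metrics, covariate joins, condition descriptives, and the
#' three simplified mixed models (daily median active temperature with a
#' random intercept; nightly minimum and torpor duration with a random
#' intercept + treatment slope).
#'
#' @param ds a `torpor_dataset`.
#' @param rc a [run_config()].
#' @return a `torpor_analysis` list: `days`, `nights`, `baselines`,
#'   `condition_summary`, `models` (list of three [simplify_model()]
#'   results), `exclusions` ledger, `bootstrap` (when requested).
#' @export
analyze_dataset <- function(ds, rc = run_config()) {
  w <- rc$windows
  days <- daily_summaries(ds, w, rc$min_median_samples) |>
    apply_carryover_exclusion(ds$schedule, rc$carryover_days, "date")
  nights <- assign_nights(ds, w, rc$max_missing_h) |>
    apply_carryover_exclusion(ds$schedule, rc$carryover_days, "night_date")
  baselines <- estimate_baseline(days, rc$threshold_offset, rc$min_active_samples)
  nights <- add_night_metrics(nights, ds, baselines, w)
  cov <- join_covariates(nights, days, ds, w)
  nights <- cov$nights
  days <- cov$days |>
    mutate(included_day = .data$included & !is.na(.data$median_active_ts))

  condition_summary <- summarize_by_condition(nights)

  day_tab <- days |> mutate(included = .data$included_day)
  models <- list(
    median_active_ts = simplify_model(day_tab,
      model_spec("median_active_ts", random = "intercept",
                 df_method = rc$df_method)),
    min_rest_ts = simplify_model(nights,
      model_spec("min_rest_ts", random = "slope", df_method = rc$df_method)),
    torpor_duration_h = simplify_model(nights,
      model_spec("torpor_duration_h", random = "slope",
                 df_method = rc$df_method))
  )

  boot <- NULL
  if (rc$n_boot > 0) {
    boot <- lapply(models[c("min_rest_ts", "torpor_duration_h")], function(m) {
      bootstrap_prediction_intervals(m$fit, n_boot = rc$n_boot,
                                     seed = rc$boot_seed)
    })
  }

  exclusions <- bind_rows(
    nights |> filter(!.data$included) |>
      transmute(record = "bird_night", bird_id = .data$bird_id,
                date = .data$night_date, reason = .data$exclusion_reason),
    days |> filter(!.data$included) |>
      transmute(record = "bird_day", bird_id = .data$bird_id,
                date = .data$date, reason = .data$exclusion_reason)
  )

  structure(list(days = days, nights = nights, baselines = baselines,
                 condition_summary = condition_summary, models = models,
                 bootstrap = boot, exclusions = exclusions,
                 config = rc),
            class = "torpor_analysis")
}

#' Run the full pipeline
#'
#' Loads or simulates the dataset per the configuration, runs
#' [analyze_dataset()], and (when `out_dir` is set) writes the tidy analysis
#' tables, baseline table, condition summaries, model summaries (CSV and
#' human-readable text), the exclusion ledger, figures, the serialised
#' configuration and a machine-readable results summary.
#'
#' @param rc a [run_config()].
#' @return the `torpor_analysis`, invisibly when writing artifacts.
#' @export
run_pipeline <- function(rc = run_config()) {
  ds <- if (!is.null(rc$data_dir)) read_dataset(rc$data_dir)
        else as_dataset(simulate_scenario(rc$scenario))
  res <- analyze_dataset(ds, rc)
  if (!is.null(rc$out_dir)) {
    write_run_artifacts(res, ds, rc)
    return(invisible(res))
  }
  res
}

write_run_artifacts <- function(res, ds, rc) {
  dir.create(rc$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(rc$out_dir, name)
  readr::write_csv(res$nights, out("bird_nights.csv"))
  readr::write_csv(res$days, out("bird_days.csv"))
  readr::write_csv(res$baselines, out("baselines.csv"))
  readr::write_csv(res$condition_summary, out("condition_summary.csv"))
  readr::write_csv(res$exclusions, out("exclusion_ledger.csv"))

  coef_tab <- bind_rows(lapply(names(res$models), function(nm) {
    res$models[[nm]]$fit$coefficients |> mutate(response = nm, .before = 1)
  }))
  readr::write_csv(coef_tab, out("model_coefficients.csv"))
  txt <- vapply(res$models, function(m) {
    paste(utils::capture.output(print(m$fit)), collapse = "\n")
  }, character(1))
  writeLines(paste(txt, collapse = "\n\n"), out("model_summaries.txt"))

  summary_json <- list(
    condition_summary = res$condition_summary,
    coefficients = coef_tab,
    n_excluded = nrow(res$exclusions)
  )
  jsonlite::write_json(summary_json, out("results.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  rc_out <- rc
  rc_out$scenario <- if (!is.null(rc$scenario)) unclass(rc$scenario)
  if (!is.null(rc_out$scenario))
    rc_out$scenario$start_date <- as.character(rc_out$scenario$start_date)
  rc_out$windows <- unclass(rc_out$windows)
  yaml::write_yaml(unclass(rc_out), out("run_config.yml"))

  if (isTRUE(rc$make_plots)) {
    p1 <- plot_trace(ds, head(ds$birds$bird_id, 2))
    ggplot2::ggsave(out("fig_traces.png"), p1, width = 9, height = 5, dpi = 150)
    p2 <- plot_condition_distributions(res$nights)
    ggplot2::ggsave(out("fig_distributions.png"), p2, width = 7, height = 4,
                    dpi = 150)
  }
  invisible(rc$out_dir)
}

#' Parameter-recovery suite across replicate scenarios
#'
#' Re-simulates the scenario under `n_seeds` different seeds, runs the full
#' pipeline on each, and aggregates the recovered condition descriptives,
#' model coefficients and baseline level against the scenario's planted
#' values. The returned report has one row per recovery target with a
#' pass/fail flag at the stated tolerance.
#'
#' @param scenario a [scenario_config()].
#' @param n_seeds number of replicate runs (default 20; fewer than 5 flags
#'   the report as low-replicate).
#' @param base_seed integer; per-replicate seeds are derived from it.
#' @param rc run configuration template (data source fields are ignored).
#' @return list with `report` (per-target summary), `runs` (per-seed
#'   metrics) and `low_replicate` flag.
#' @export
recovery_suite <- function(scenario = scenario_preset(), n_seeds = 20,
                           base_seed = 1, rc = run_config()) {
  runs <- lapply(seq_len(n_seeds), function(i) {
    cfg <- scenario
    cfg$rng_seed <- as.integer((base_seed + 7919 * i) %% 2147483647L)
    res <- analyze_dataset(as_dataset(simulate_scenario(cfg)), rc)
    run_metrics(res)
  })
  runs <- bind_rows(runs, .id = "replicate")
  agg <- runs |>
    group_by(.data$metric) |>
    summarise(value = mean(.data$value, na.rm = TRUE),
              n_total = sum(.data$n), .groups = "drop")

  expected <- recovery_targets(scenario)
  report <- left_join(expected, agg, by = "metric") |>
    mutate(pass = abs(.data$value - .data$expected) <= .data$tolerance)
  list(report = report, runs = runs, low_replicate = n_seeds < 5)
}

# Per-run recovered quantities, one row per metric.
run_metrics <- function(res) {
  cs <- res$condition_summary
  g <- function(cond, col) {
    v <- cs[[col]][cs$condition == cond]
    if (length(v)) v else NA_real_
  }
  n_cond <- function(cond) {
    v <- cs$n_nights[cs$condition == cond]
    if (length(v)) v else 0L
  }
  coef_of <- function(model, term) {
    cf <- res$models[[model]]$fit$coefficients
    v <- cf$estimate[cf$term == term]
    if (length(v)) v[1] else NA_real_
  }
  n_obs <- function(model) res$models[[model]]$fit$n_observations
  bl <- res$baselines |> filter(.data$usable)
  tibble(
    metric = c("control_min_ts", "treatment_min_ts",
               "control_duration", "treatment_duration",
               "treatment_effect_min_ts", "treatment_effect_duration",
               "ta_slope_daytime", "baseline_normothermic"),
    value = c(g("control", "min_ts_mean"), g("treatment", "min_ts_mean"),
              g("control", "duration_mean"), g("treatment", "duration_mean"),
              coef_of("min_rest_ts", "treatment"),
              coef_of("torpor_duration_h", "treatment"),
              coef_of("median_active_ts", "ta"),
              mean(bl$normothermic_ts)),
    n = c(n_cond("control"), n_cond("treatment"),
          n_cond("control"), n_cond("treatment"),
          n_obs("min_rest_ts"), n_obs("torpor_duration_h"),
          n_obs("median_active_ts"), nrow(bl))
  )
}

# Planted/derived expectations for the recovery report.
recovery_targets <- function(cfg) {
  tibble(
    metric = c("control_min_ts", "treatment_min_ts",
               "control_duration", "treatment_duration",
               "treatment_effect_min_ts", "treatment_effect_duration",
               "ta_slope_daytime", "baseline_normothermic"),
    expected = c(cfg$control_min_ts_mean,
                 cfg$control_min_ts_mean + cfg$treatment_effect_min_ts,
                 cfg$control_torpor_duration_mean,
                 cfg$control_torpor_duration_mean + cfg$treatment_effect_duration,
                 cfg$treatment_effect_min_ts,
                 cfg$treatment_effect_duration,
                 cfg$ta_slope_daytime,
                 cfg$resting_normothermic_mean),
    tolerance = c(0.3, 0.3, 0.5, 0.5, 0.3, 0.5, 0.05, 0.3)
  )
}

#' @export
print.torpor_analysis <- function(x, ...) {
  cat("<torpor_analysis>\n")
  cat(sprintf("  %d bird-nights (%d included), %d bird-days, %d exclusions\n",
              nrow(x$nights), sum(x$nights$included), nrow(x$days),
              nrow(x$exclusions)))
  print(x$condition_summary)
  invisible(x)
}
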