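#' Build the alternating-block treatment schedule
#'
#' Assigns each site a sequence of control and treatment blocks of
#' `block_length_days` days. The two sequences are complementary: on any date
#' the first site is in the opposite condition to the second, so daily weather
#' is never confounded with condition across the study.
#'
#' @param cfg a [scenario_config()].
#' @param first_condition_site1 condition of site 1's first block
#'   (`"treatment"` or `"control"`); site 2 starts with the complement.
#' @return a tibble with columns `site`, `date`, `condition`
#'   (factor, levels `control` < `treatment`), and `block` (1-based index).
#' @export
#' @examples
#' sched <- make_schedule(scenario_config())
#' table(sched$site, sched$condition)
make_schedule <- function(cfg, first_condition_site1 = "treatment") {
  validate_scenario(cfg)
  first_condition_site1 <- match.arg(first_condition_site1, c("treatment", "control"))
  dates <- cfg$start_date + seq_len(cfg$n_days) - 1
  block <- (seq_len(cfg$n_days) - 1) %/% cfg$block_length_days + 1
  odd <- block %% 2 == 1
  seq1 <- ifelse(odd, first_condition_site1,
                 setdiff(c("treatment", "control"), first_condition_site1))
  seq2 <- ifelse(seq1 == "treatment", "control", "treatment")
  sites <- site_ids(cfg$n_sites)
  out <- lapply(seq_len(cfg$n_sites), function(i) {
    cond <- if (i %% 2 == 1) seq1 else seq2
    tibble(site = sites[i], date = dates,
           condition = factor(cond, levels = c("control", "treatment")),
           block = block)
  })
  bind_rows(out)
}

site_ids <- function(n) sprintf("S%d", seq_len(n))

#' Dates removed by the carry-over rule
#'
#' For one site's schedule, returns the dates falling in the first
#' `carryover_days` days of any control block that immediately follows a
#' treatment block. A leading control block (not preceded by treatment) is
#' untouched.
#'
#' @param schedule_site schedule rows for a single site, ordered by date.
#' @param carryover_days number of leading control days to drop (default 2).
#' @return a `Date` vector (possibly empty).
#' @export
carryover_dates <- function(schedule_site, carryover_days = 2) {
  stopifnot(length(unique(schedule_site$site)) <= 1)
  s <- schedule_site[order(schedule_site$date), ]
  runs <- rle(as.character(s$condition))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  drop <- as.Date(character(0))
  for (k in seq_along(runs$values)) {
    if (runs$values[k] == "control" && k > 1 && runs$values[k - 1] == "treatment") {
      idx <- starts[k]:min(ends[k], starts[k] + carryover_days - 1)
      drop <- c(drop, s$date[idx])
    }
  }
  drop
}
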