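#' Fit a cubic calibration curve for one transmitter
#'
#' Temperature-sensitive transmitters encode temperature in the interval
#' between radio pulses; each transmitter is bench-calibrated against known
#' temperatures and the pulse-interval -> temperature relation is summarised
#' by a least-squares 3rd-order polynomial. The fitted polynomial must be
#' strictly monotone over the calibrated pulse range so that the relation is
#' invertible; a non-monotone fit is rejected.
#'
#' @param points data frame with columns `pulse_interval_ms` and
#'   `temperature_c` (at least 5 distinct pulse values).
#' @param transmitter_id identifier stored with the curve.
#' @param r2_warn R-squared below which a quality warning is flagged
#'   (default 0.99).
#' @return a `calibration_curve`: list with `transmitter_id`, `coefficients`
#'   (length 4, increasing powers of pulse interval), `pulse_range`,
#'   `r_squared`, `n_points`, `low_r2` flag.
#' @export
#' @examples
#' pts <- data.frame(pulse_interval_ms = seq(800, 1200, 100),
#'                   temperature_c = 40 - 0.01 * seq(800, 1200, 100))
#' fit_calibration(pts, "tx01")$r_squared
fit_calibration <- function(points, transmitter_id, r2_warn = 0.99) {
  stopifnot(all(c("pulse_interval_ms", "temperature_c") %in% names(points)))
  p <- points$pulse_interval_ms
  t <- points$temperature_c
  keep <- !is.na(p) & !is.na(t)
  p <- p[keep]; t <- t[keep]
  if (length(unique(p)) < 5) {
    stop("calibration for ", transmitter_id,
         " needs >= 5 distinct pulse values (got ", length(unique(p)), ")")
  }
  # fit on a centred/scaled pulse variable (raw ms powers reach 1e9 and the
  # normal equations lose ~8 digits), then expand back to raw coefficients
  ctr <- mean(range(p))
  scl <- max(diff(range(p)) / 2, 1)
  z <- (p - ctr) / scl
  fit <- lm(t ~ z + I(z^2) + I(z^3))
  cf <- expand_scaled_cubic(unname(coef(fit)), ctr, scl)
  rng <- range(p)
  # monotonicity of the fitted cubic over the calibrated range, dense grid
  grid <- seq(rng[1], rng[2], length.out = 512)
  deriv <- cf[2] + 2 * cf[3] * grid + 3 * cf[4] * grid^2
  if (!(all(deriv > 0) || all(deriv < 0))) {
    stop("calibration fit for ", transmitter_id,
         " is not monotone over [", signif(rng[1], 6), ", ", signif(rng[2], 6),
         "] ms; derivative changes sign")
  }
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((t - mean(t))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  low <- r2 < r2_warn
  if (low) warning("calibration R^2 for ", transmitter_id, " is ",
                   signif(r2, 4), " (< ", r2_warn, ")")
  structure(list(transmitter_id = transmitter_id,
                 coefficients = cf,
                 pulse_range = rng,
                 r_squared = r2,
                 n_points = length(p),
                 low_r2 = low),
            class = "calibration_curve")
}

#' Convert pulse intervals to skin temperatures
#'
#' Evaluates a transmitter's fitted cubic. Pulses outside the calibrated
#' range (extended by `margin`, a fraction of the range width on each side)
#' become `NA`: cubic extrapolation is unbounded and a single out-of-range
#' pulse could otherwise fabricate a torpor bout. The number of out-of-range
#' pulses is attached as attribute `n_out_of_range`.
#'
#' @param curve a `calibration_curve` from [fit_calibration()].
#' @param pulse_ms numeric vector of pulse intervals (ms).
#' @param margin fractional range extension tolerated (default 0.05).
#' @return temperatures in C with `NA` where out of range.
#' @export
pulse_to_temperature <- function(curve, pulse_ms, margin = 0.05) {
  stopifnot(inherits(curve, "calibration_curve"))
  rng <- curve$pulse_range
  pad <- margin * diff(rng)
  ok <- !is.na(pulse_ms) & pulse_ms >= rng[1] - pad & pulse_ms <= rng[2] + pad
  cf <- curve$coefficients
  out <- rep(NA_real_, length(pulse_ms))
  p <- pulse_ms[ok]
  out[ok] <- cf[1] + cf[2] * p + cf[3] * p^2 + cf[4] * p^3
  structure(out, n_out_of_range = sum(!ok & !is.na(pulse_ms)))
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve %s> %d points, R^2 = %.4f, pulses %.1f-%.1f ms\n",
              x$transmitter_id, x$n_points, x$r_squared,
              x$pulse_range[1], x$pulse_range[2]))
  invisible(x)
}

#' Serialize / read calibration curves as a text table
#'
#' @param curves list of `calibration_curve` objects.
#' @param path CSV path.
#' @return `write_calibration_curves()` returns `path` invisibly;
#'   `read_calibration_curves()` a named list of curves.
#' @export
write_calibration_curves <- function(curves, path) {
  rows <- lapply(curves, function(cv) {
    tibble(transmitter_id = cv$transmitter_id,
           c0 = cv$coefficients[1], c1 = cv$coefficients[2],
           c2 = cv$coefficients[3], c3 = cv$coefficients[4],
           pulse_min_ms = cv$pulse_range[1], pulse_max_ms = cv$pulse_range[2],
           r_squared = cv$r_squared, n_points = cv$n_points)
  })
  readr::write_csv(bind_rows(rows), path)
  invisible(path)
}

#' @rdname write_calibration_curves
#' @export
read_calibration_curves <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  curves <- lapply(seq_len(nrow(tab)), function(i) {
    structure(list(transmitter_id = tab$transmitter_id[i],
                   coefficients = c(tab$c0[i], tab$c1[i], tab$c2[i], tab$c3[i]),
                   pulse_range = c(tab$pulse_min_ms[i], tab$pulse_max_ms[i]),
                   r_squared = tab$r_squared[i],
                   n_points = tab$n_points[i],
                   low_r2 = tab$r_squared[i] < 0.99),
              class = "calibration_curve")
  })
  setNames(curves, tab$transmitter_id)
}

# ---- generator-side true transmitter curves -------------------------------

# A true transmitter response is a strictly decreasing cubic in pulse
# interval over ~600-1400 ms spanning roughly -1 to 51 C (so the 5-45 C
# bench calibration range is always interior), with small random
# per-transmitter shape perturbations. Coefficients are drawn in a scaled
# variable z = (p - 1000)/400 and expanded to raw-pulse powers.
make_true_curve <- function() {
  repeat {
    a <- c(25 + rnorm(1, 0, 1), -26 + rnorm(1, 0, 1), rnorm(1, 0, 0.5), rnorm(1, 0, 0.5))
    # monotone decreasing on z in [-1, 1]: a1 + 2 a2 z + 3 a3 z^2 < 0
    z <- seq(-1, 1, length.out = 201)
    if (all(a[2] + 2 * a[3] * z + 3 * a[4] * z^2 < 0)) break
  }
  raw <- expand_scaled_cubic(a, 1000, 400)
  pulse_grid <- seq(600, 1400, length.out = 4001)
  temp_grid <- raw[1] + raw[2] * pulse_grid + raw[3] * pulse_grid^2 +
    raw[4] * pulse_grid^3
  list(coefficients = raw, pulse_grid = pulse_grid, temp_grid = temp_grid)
}

# Invert a true curve: temperature -> pulse interval, by monotone
# interpolation on the dense grid (error << 0.001 C over the working range).
true_temp_to_pulse <- function(true_curve, temp_c) {
  approx(x = rev(true_curve$temp_grid), y = rev(true_curve$pulse_grid),
         xout = temp_c, rule = 2)$y
}

true_pulse_to_temp <- function(true_curve, pulse_ms) {
  cf <- true_curve$coefficients
  cf[1] + cf[2] * pulse_ms + cf[3] * pulse_ms^2 + cf[4] * pulse_ms^3
}

# Bench calibration points for a true curve: known temperatures 5-45 C in
# 5 C steps, pulse read with small timing noise.
make_calibration_points <- function(true_curve, transmitter_id,
                                    temps = seq(5, 45, by = 5),
                                    pulse_noise_ms = 0.02) {
  pulses <- true_temp_to_pulse(true_curve, temps) + rnorm(length(temps), 0, pulse_noise_ms)
  tibble(transmitter_id = transmitter_id,
         pulse_interval_ms = pulses,
         temperature_c = temps)
}
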