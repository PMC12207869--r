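# Small numeric helpers shared across the package.

#' Truncated-normal draws by inverse-CDF
#'
#' Deterministic given the RNG stream; used wherever the generator needs a
#' bounded draw (e.g. a planted nightly minimum that must lie below the torpor
#' threshold).
#'
#' @param n number of draws.
#' @param mean,sd normal parameters (vectorised).
#' @param lower,upper truncation bounds (vectorised; `-Inf`/`Inf` allowed).
#' @return numeric vector of length `n`.
#' @keywords internal
rtrunc_norm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  u <- runif(n)
  p_lo <- pnorm(lower, mean, sd)
  p_hi <- pnorm(upper, mean, sd)
  # guard against zero-width intervals from extreme bounds
  p_hi <- pmax(p_hi, p_lo + 1e-12)
  qnorm(p_lo + u * (p_hi - p_lo), mean, sd)
}

# Half-cosine ramp from y0 at h0 to y1 at h1 (zero slope at both ends).
half_cos_ramp <- function(h, h0, h1, y0, y1) {
  f <- (h - h0) / max(h1 - h0, 1e-9)
  y0 + (y1 - y0) * (1 - cos(pi * pmin(pmax(f, 0), 1))) / 2
}

# Quarter-cosine fall: y0 at h0 (zero slope) down to y1 at h1 (non-zero slope).
quarter_cos_fall <- function(h, h0, h1, y0, y1) {
  f <- (h - h0) / max(h1 - h0, 1e-9)
  y1 + (y0 - y1) * cos(pi / 2 * pmin(pmax(f, 0), 1))
}

# Quarter-sine rise: y0 at h0 (non-zero slope) up to y1 at h1 (zero slope).
quarter_sin_rise <- function(h, h0, h1, y0, y1) {
  f <- (h - h0) / max(h1 - h0, 1e-9)
  y0 + (y1 - y0) * sin(pi / 2 * pmin(pmax(f, 0), 1))
}

# Hour-of-day (fractional) of a POSIXct stored in UTC clock time.
hour_of <- function(time) {
  (as.numeric(time) %% 86400) / 3600
}

# Calendar date of a UTC-clock POSIXct.
date_of <- function(time) {
  as.Date(as.POSIXlt(time, tz = "UTC"))
}

# POSIXct at a fractional clock hour of a given date (UTC clock convention).
at_hour <- function(date, hour) {
  as.POSIXct(as.numeric(as.POSIXct(paste(date, "00:00:00"), tz = "UTC")) +
               hour * 3600, origin = "1970-01-01", tz = "UTC")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Expand a cubic in z = (x - center)/scale into coefficients of raw powers
# of x (length-4 vector, increasing powers). Fitting in z keeps the normal
# equations well-conditioned; raw coefficients are the external contract.
expand_scaled_cubic <- function(a, center, scale) {
  raw <- numeric(4)
  for (k in 0:3) {
    ak <- a[k + 1] / scale^k
    for (j in 0:k) {
      raw[j + 1] <- raw[j + 1] + ak * choose(k, j) * (-center)^(k - j)
    }
  }
  raw
}
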