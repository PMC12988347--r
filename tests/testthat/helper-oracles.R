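# Independent oracles used across the suite. These deliberately re-derive
# quantities from first principles (minute-resolution integration, crossing
# search, hand-rolled quantiles) without calling the package's own code
# paths, so that agreement is evidence rather than tautology.

# Solar elevation (degrees) from the standard declination / hour-angle
# formulas, written out independently of R/solar.R.
oracle_elevation <- function(lat, lon, utc_offset, date, hour_local) {
  doy <- as.integer(strftime(as.Date(date), "%j"))
  g <- 2 * pi / 365 * (doy - 1 + (hour_local - 12) / 24)
  eot <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                     0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  tst_min <- (hour_local * 60 + eot + 4 * lon - 60 * utc_offset) %% 1440
  ha <- (tst_min / 4 - 180) * pi / 180
  latr <- lat * pi / 180
  sinel <- sin(latr) * sin(decl) + cos(latr) * cos(decl) * cos(ha)
  asin(pmin(1, pmax(-1, sinel))) * 180 / pi
}

# Sunrise/sunset by minute-resolution crossing search of the elevation
# through -0.833 degrees, with linear interpolation between minutes.
oracle_sun_times <- function(lat, lon, utc_offset, date) {
  h <- seq(0, 24, by = 1 / 60)
  el <- oracle_elevation(lat, lon, utc_offset, date, h) + 0.833
  s <- sign(el)
  up <- which(s[-1] > 0 & s[-length(s)] <= 0)
  down <- which(s[-1] <= 0 & s[-length(s)] > 0)
  cross <- function(i) h[i] + (0 - el[i]) / (el[i + 1] - el[i]) / 60
  list(sunrise = if (length(up)) cross(up[1]) else NA,
       sunset = if (length(down)) cross(down[1]) else NA)
}

# Hand-rolled type-7 quantile and Tukey-fence filter.
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p
  lo <- floor(h)
  x[lo + 1] + (h - lo) * (x[pmin(lo + 2, length(x))] - x[lo + 1])
}

oracle_tukey_keep <- function(x) {
  q1 <- oracle_quantile7(x, 0.25)
  q3 <- oracle_quantile7(x, 0.75)
  iqr <- q3 - q1
  x[x >= q1 - 1.5 * iqr & x <= q3 + 1.5 * iqr]
}

# Minute-resolution noiseless integration of the generator equations
# (temperature harmonic, elevation-driven GPP, gamma substrate kernel,
# two-component exponential respiration). Returns day/night mean Rs with
# day defined by positive solar elevation.
oracle_generator_day_night <- function(lat = 45, lon = -90, utc_offset = -6,
                                       start = as.Date("2012-06-01"),
                                       days = 92,
                                       mean_ts = 18, amp = 2, phase = 3,
                                       gpp_max = 15,
                                       lag_mean = 8, lag_shape = 12,
                                       beta_root = log(2) / 10,
                                       beta_het = log(2) / 10,
                                       base_root = 0.04, base_het = 0.6) {
  step <- 1 / 60                                  # hours
  warm <- 2
  n_h <- (days + warm) * 24
  t <- seq(0, n_h - step, by = step)              # hours since warm start
  date <- start - warm + floor(t / 24)
  hod <- t %% 24
  t_solar <- hod + lon / 15 - utc_offset
  ts <- mean_ts + amp * sin(2 * pi * (t_solar - 6 - phase) / 24)
  el <- oracle_elevation(lat, lon, utc_offset, date, hod)
  gpp <- gpp_max * pmax(0, sin(el * pi / 180))
  tau <- seq(0, 48, by = step)
  k <- dgamma(tau, shape = lag_shape, scale = lag_mean / lag_shape)
  k <- k / sum(k)
  S <- stats::filter(gpp, k, method = "convolution", sides = 1)
  S <- as.numeric(S); S[is.na(S)] <- 0
  rs <- base_root * S * exp(beta_root * ts) + base_het * exp(beta_het * ts)
  keep <- date >= start
  day <- el > 0
  list(day_mean = mean(rs[keep & day]), night_mean = mean(rs[keep & !day]))
}

# Small fully-covered labelled series built by hand for QC/diel unit tests.
toy_labeled_series <- function(days = 20, rs_day = 2, rs_night = 3,
                               ts_day = 20, ts_night = 16,
                               start = as.Date("2012-06-01")) {
  rows <- lapply(seq_len(days) - 1, function(d) {
    data.frame(
      date = start + d,
      hour = 0:23,
      period = rep(c("night", "day", "night"), c(6, 12, 6)),
      diel_date = c(rep(start + d - 1, 6), rep(start + d, 18)),
      rs = rep(c(rs_night, rs_day, rs_night), c(6, 12, 6)),
      ts = rep(c(ts_night, ts_day, ts_night), c(6, 12, 6)),
      treatment = "none")
  })
  do.call(rbind, rows)
}
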