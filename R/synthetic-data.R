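# Mechanistic synthetic generator for COSORE-like hourly chamber series.
#
# Soil temperature follows a diurnal harmonic in solar-local time; canopy
# carbon uptake (GPP) follows solar elevation scaled by an AR(1) day-to-day
# multiplier; a gamma substrate-supply kernel delays the arrival of
# photosynthate at the roots/rhizosphere; root and heterotrophic respiration
# respond exponentially to temperature with separate sensitivities; chamber
# noise is multiplicative lognormal. Everything is driven by one RNG seed so
# identical configs reproduce identical series bit-for-bit.

#' Configuration for the synthetic flux-series generator
#'
#' Defaults describe a temperate broadleaf forest summer with a mid-day GPP
#' peak, an 8-hour photosynthate supply lag, a 3-hour lag of peak soil
#' temperature behind solar noon, and both respiration components at
#' Q10 = 2 (beta = ln 2 / 10 per degree C).
#'
#' @param site_id site identifier string.
#' @param lat,lon site coordinates, decimal degrees.
#' @param utc_offset site standard time minus UTC, hours.
#' @param start_date,end_date first and last simulated calendar dates.
#' @param mean_ts,ts_amplitude mean and diurnal half-amplitude of soil
#'   temperature, degrees C.
#' @param ts_phase_lag hours by which peak soil temperature trails solar noon.
#' @param gpp_max canopy uptake at solar zenith with unit daily scale,
#'   umol CO2 m-2 s-1. Set to 0 to switch the substrate pathway off.
#' @param gpp_day_ar1 AR(1) coefficient of the log day-to-day GPP multiplier.
#' @param gpp_day_cv coefficient of variation of that multiplier.
#' @param lag_mean mean of the gamma substrate-supply kernel, hours.
#'   `lag_mean = 0` collapses the kernel to a same-hour delta.
#' @param lag_shape gamma shape of the kernel (>= 4 gives a well-defined
#'   unimodal peak).
#' @param beta_root,beta_het temperature sensitivities, per degree C
#'   (Q10 = exp(10 * beta)).
#' @param base_root basal root respiration per unit substrate flux at 0 C.
#' @param base_het basal heterotrophic respiration at 0 C, umol m-2 s-1.
#' @param priming_coef rhizosphere priming: fractional increase of
#'   heterotrophic respiration per unit substrate flux.
#' @param night_base_factor multiplier applied to the basal flux of both
#'   components while the sun is below the horizon; 1 means no diel
#'   asymmetry beyond temperature and substrate.
#' @param noise_cv coefficient of variation of multiplicative lognormal
#'   chamber noise (mean 1).
#' @param swc_mean,swc_amplitude mean and seasonal half-amplitude of soil
#'   water content, percent.
#' @param seed integer RNG seed.
#' @return a `generator_config` list, validated.
#' @export
generator_config <- function(site_id = "synth01",
                             lat = 45, lon = -90, utc_offset = -6,
                             start_date = "2012-06-01",
                             end_date = "2012-08-31",
                             mean_ts = 18, ts_amplitude = 2, ts_phase_lag = 3,
                             gpp_max = 15, gpp_day_ar1 = 0.6,
                             gpp_day_cv = 0.25,
                             lag_mean = 8, lag_shape = 12,
                             beta_root = log(2) / 10, beta_het = log(2) / 10,
                             base_root = 0.04, base_het = 0.6,
                             priming_coef = 0, night_base_factor = 1,
                             noise_cv = 0.1,
                             swc_mean = 25, swc_amplitude = 3,
                             seed = 1L) {
  cfg <- list(site_id = site_id, lat = lat, lon = lon,
              utc_offset = utc_offset,
              start_date = as.Date(start_date), end_date = as.Date(end_date),
              mean_ts = mean_ts, ts_amplitude = ts_amplitude,
              ts_phase_lag = ts_phase_lag,
              gpp_max = gpp_max, gpp_day_ar1 = gpp_day_ar1,
              gpp_day_cv = gpp_day_cv,
              lag_mean = lag_mean, lag_shape = lag_shape,
              beta_root = beta_root, beta_het = beta_het,
              base_root = base_root, base_het = base_het,
              priming_coef = priming_coef,
              night_base_factor = night_base_factor,
              noise_cv = noise_cv,
              swc_mean = swc_mean, swc_amplitude = swc_amplitude,
              seed = as.integer(seed))
  stopifnot(cfg$ts_amplitude >= 0, cfg$swc_amplitude >= 0,
            cfg$lag_mean >= 0, cfg$noise_cv >= 0, cfg$gpp_max >= 0,
            cfg$night_base_factor > 0,
            cfg$end_date > cfg$start_date, abs(cfg$lat) <= 90)
  class(cfg) <- "generator_config"
  cfg
}

#' A generator configuration with no diel mechanism
#'
#' Convenience wrapper for null-hypothesis simulations: the substrate pathway
#' is off (no photosynthate lag), the soil-temperature harmonic peaks at
#' 18:00 solar so daytime and nighttime mean temperatures are equal at the
#' equator, and both components share one temperature sensitivity. Under this
#' configuration the expected day-night flux difference is zero and any
#' detected difference is a false positive.
#'
#' @param seed integer RNG seed.
#' @param ... overrides passed on to [generator_config()].
#' @export
null_config <- function(seed = 1L, ...) {
  generator_config(lat = 0, lon = 0, utc_offset = 0,
                   gpp_max = 0, base_root = 0, lag_mean = 0,
                   ts_phase_lag = 6,   # Ts peak at 18:00 solar: equal means
                   beta_root = log(2) / 10, beta_het = log(2) / 10,
                   seed = seed, ...)
}

# Discretised gamma substrate-supply kernel over lags 0..max_lag hours.
# Bin tau carries the gamma mass of [tau - 0.5, tau + 0.5); mass is
# renormalised to 1 so no substrate is lost to truncation.
substrate_kernel <- function(lag_mean, lag_shape, max_lag = 48) {
  tau <- 0:max_lag
  if (lag_mean <= 0) {
    w <- c(1, rep(0, max_lag))
  } else {
    scale <- lag_mean / lag_shape
    edges <- c(0, tau + 0.5)
    w <- diff(stats::pgamma(edges, shape = lag_shape, scale = scale))
  }
  w / sum(w)
}

#' Generate one synthetic site
#'
#' Simulates an hourly chamber flux series over the configured date range,
#' plus daily GPP totals and a ground-truth record for test oracles.
#'
#' The construction, per hour t (solar-local time used internally;
#' timestamps reported in site standard time):
#' \itemize{
#'   \item Ts(t) = mean_ts + ts_amplitude * sin(2 pi (t - 6 - ts_phase_lag) / 24)
#'   \item GPP(t) = gpp_max * m_d * max(0, sin(solar elevation)), with m_d a
#'     lognormal AR(1) day-to-day multiplier of mean 1
#'   \item S(t) = sum_tau k(tau) GPP(t - tau), gamma kernel of mean
#'     `lag_mean` and shape `lag_shape`, unit mass over 0-48 h
#'   \item Rroot(t) = base_root * S(t) * exp(beta_root Ts(t))
#'   \item Rh(t) = base_het * (1 + priming_coef S(t)) * exp(beta_het Ts(t))
#'   \item Rs(t) = (Rroot + Rh) * night_base_factor^[sun below horizon] * eps(t),
#'     eps lognormal, mean 1, CV `noise_cv`
#' }
#'
#' @param config a [generator_config()].
#' @return list with elements `series` (hourly data.frame: `timestamp`,
#'   `date`, `hour`, `rs`, `ts`, `swc`, `gpp`, `rroot`, `rh`, `port`,
#'   `treatment`), `gpp_daily` (data.frame `date`, `gpp_gC_m2_d`), `meta`
#'   (a [make_site_meta()] record) and `truth` (true component Q10s, lag,
#'   expected sign of the night-minus-day flux difference from a noiseless
#'   run, and the noiseless component series).
#' @export
generate_site <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  set.seed(cfg$seed)

  dates <- seq(cfg$start_date, cfg$end_date, by = "day")
  n_days <- length(dates)
  # two warm-up days so the 48-h substrate convolution is fully spun up
  warm <- 2L
  all_dates <- seq(cfg$start_date - warm, cfg$end_date, by = "day")
  hour <- rep(0:23, times = length(all_dates))
  date <- rep(all_dates, each = 24)
  n <- length(hour)

  # solar-local clock: offset of mean solar time from site standard time
  solar_off <- cfg$lon / 15 - cfg$utc_offset
  t_solar <- (hour + 0.5) + solar_off
  ts <- cfg$mean_ts + cfg$ts_amplitude *
    sin(2 * pi * (t_solar - 6 - cfg$ts_phase_lag) / 24)

  elev <- solar_elevation(cfg$lat, cfg$lon, cfg$utc_offset, date, hour + 0.5)
  light <- pmax(0, sin(deg2rad(elev)))
  if (all(light == 0) && cfg$gpp_max > 0) {
    stop("no daylight in simulated range (polar night?) starting ",
         format(all_dates[1]))
  }

  # lognormal AR(1) day multiplier, mean 1
  sdlog <- sqrt(log(1 + cfg$gpp_day_cv^2))
  z <- numeric(length(all_dates))
  z[1] <- stats::rnorm(1, 0, sdlog)
  if (length(z) > 1) {
    innov <- stats::rnorm(length(z) - 1, 0, sdlog * sqrt(1 - cfg$gpp_day_ar1^2))
    for (d in 2:length(z)) z[d] <- cfg$gpp_day_ar1 * z[d - 1] + innov[d - 1]
  }
  m_day <- exp(z - sdlog^2 / 2)
  gpp <- cfg$gpp_max * m_day[match(date, all_dates)] * light

  kern <- substrate_kernel(cfg$lag_mean, cfg$lag_shape)
  S <- stats::filter(gpp, kern, method = "convolution", sides = 1)
  S <- as.numeric(S)
  S[is.na(S)] <- 0   # only within the warm-up window

  rroot <- cfg$base_root * S * exp(cfg$beta_root * ts)
  rh <- cfg$base_het * (1 + cfg$priming_coef * S) * exp(cfg$beta_het * ts)
  night <- elev <= 0
  basefac <- ifelse(night, cfg$night_base_factor, 1)
  clean <- (rroot + rh) * basefac

  if (cfg$noise_cv > 0) {
    s2 <- log(1 + cfg$noise_cv^2)
    eps <- stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
  } else {
    eps <- rep(1, n)
  }
  rs <- clean * eps

  doy <- as.integer(strftime(date, "%j"))
  swc <- cfg$swc_mean + cfg$swc_amplitude *
    sin(2 * pi * (doy - min(doy)) / 365)

  keep <- date >= cfg$start_date
  series <- data.frame(
    timestamp = as.POSIXct(paste0(format(date), " ", sprintf("%02d", hour),
                                  ":00:00"), tz = "UTC"),
    date = date, hour = hour,
    rs = rs, ts = ts, swc = swc, gpp = gpp,
    rroot = rroot * basefac, rh = rh * basefac,
    port = "P1", treatment = "none",
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(series) <- NULL

  # daily GPP total: umol m-2 s-1 averaged over each hour -> g C m-2 d-1
  gpp_daily <- stats::aggregate(gpp ~ date, data = series,
                                FUN = function(x) sum(x) * 3600 * 12 * 1e-6)
  names(gpp_daily)[2] <- "gpp_gC_m2_d"

  clean_kept <- clean[keep]
  night_kept <- night[keep]
  d_clean <- mean(clean_kept[night_kept]) - mean(clean_kept[!night_kept])
  truth <- list(
    true_Q10_root = exp(10 * cfg$beta_root),
    true_Q10_het = exp(10 * cfg$beta_het),
    lag_mean = cfg$lag_mean,
    expected_sign_dRs = sign(round(d_clean, 10)),
    clean_rs = clean_kept)

  meta <- make_site_meta(cfg$site_id, cfg$lat, cfg$lon, cfg$utc_offset, "DBF")
  list(series = series, gpp_daily = gpp_daily, meta = meta, truth = truth)
}

#' Write a synthetic site to COSORE-like CSV/YAML files
#'
#' Produces `<site_id>_flux.csv` (columns `timestamp_iso, port,
#' rs_umol_m2_s, ts_C_5cm, swc_pct_5cm, treatment`), `<site_id>_meta.yaml`,
#' and, when the series carries component columns, `<site_id>_partition.csv`
#' with an added `rh_umol_m2_s` column and `<site_id>_gpp.csv` with daily
#' GPP totals. The files round-trip losslessly through [read_flux_table()].
#'
#' @param site a list as returned by [generate_site()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cosore_like <- function(site, dir) {
  if (nrow(site$series) == 0) stop("empty series")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- site$series
  id <- site$meta$site_id
  flux <- data.frame(
    timestamp_iso = strftime(s$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    port = s$port,
    rs_umol_m2_s = s$rs,
    ts_C_5cm = s$ts,
    swc_pct_5cm = s$swc,
    treatment = s$treatment)
  paths <- c(flux = file.path(dir, paste0(id, "_flux.csv")))
  utils::write.csv(flux, paths["flux"], row.names = FALSE)
  meta_path <- file.path(dir, paste0(id, "_meta.yaml"))
  yaml::write_yaml(list(site_id = id, lat = site$meta$lat,
                        lon = site$meta$lon,
                        utc_offset = site$meta$utc_offset,
                        igbp = site$meta$igbp), meta_path)
  paths["meta"] <- meta_path
  if (all(c("rh", "rroot") %in% names(s))) {
    part <- cbind(flux, rh_umol_m2_s = s$rh)
    paths["partition"] <- file.path(dir, paste0(id, "_partition.csv"))
    utils::write.csv(part, paths["partition"], row.names = FALSE)
  }
  if (!is.null(site$gpp_daily)) {
    gd <- data.frame(date = format(site$gpp_daily$date),
                     gpp_gC_m2_d = site$gpp_daily$gpp_gC_m2_d)
    paths["gpp"] <- file.path(dir, paste0(id, "_gpp.csv"))
    utils::write.csv(gd, paths["gpp"], row.names = FALSE)
  }
  invisible(paths)
}
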