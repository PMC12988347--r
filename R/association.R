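# Model-II (standardized major axis) regression and the GPP linkage
# analyses: cross-site day-vs-night comparison, Rs-GPP relationships and
# lagged correlation profiles.

#' Standardized major axis (model II) regression
#'
#' Symmetric line fit appropriate when both variables carry error:
#' slope = sign(r) * sd(y) / sd(x), intercept = mean(y) - slope * mean(x).
#' The 95% confidence interval follows the standard SMA construction
#' slope * (sqrt(B + 1) +/- sqrt(B)) with
#' B = F(0.95; 1, n - 2) * (1 - r^2) / (n - 2).
#'
#' @param x,y numeric vectors of equal length, n >= 3, non-zero variance.
#' @return list: `slope`, `intercept`, `r`, `r2`, `n`, `slope_ci_low`,
#'   `slope_ci_high`.
#' @export
sma_fit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("SMA needs at least 3 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in SMA input")
  }
  r <- stats::cor(x, y)
  s <- if (r < 0) -1 else 1
  slope <- s * stats::sd(y) / stats::sd(x)
  B <- stats::qf(0.95, 1, n - 2) * (1 - r^2) / (n - 2)
  ci <- slope * (sqrt(B + 1) + c(-1, 1) * sqrt(B))
  list(slope = slope, intercept = mean(y) - slope * mean(x),
       r = r, r2 = r^2, n = n,
       slope_ci_low = min(ci), slope_ci_high = max(ci))
}

#' Cross-site SMA of nighttime versus daytime mean fluxes
#'
#' x is the site mean daytime Rs, y the site mean nighttime Rs; a slope
#' above 1 means the nighttime excess grows with flux magnitude.
#'
#' @param site_means data.frame with `day_mean_rs` and `night_mean_rs`, one
#'   row per site.
#' @return [sma_fit()] result.
#' @export
day_night_sma <- function(site_means) {
  if (nrow(site_means) < 3) stop("need at least 3 sites for SMA")
  sma_fit(site_means$day_mean_rs, site_means$night_mean_rs)
}

#' Lagged correlation profile of daily Rs against daily GPP
#'
#' Pearson correlation of Rs(t) with GPP(t - l) for lags l = 0..`max_lag`
#' days; the profile peak identifies the substrate-supply delay. Lags with
#' fewer than `min_pairs` complete pairs are NA. Ties at the peak go to the
#' smallest lag.
#'
#' @param rs_daily data.frame with `date` and an `rs` column (daily mean).
#' @param gpp_daily data.frame with `date` and `gpp_gC_m2_d` (or `gpp`).
#' @param max_lag maximum lag in days (default 45).
#' @param min_pairs minimum complete pairs per lag (default 10).
#' @return list: `lags`, `r_by_lag`, `peak_lag`, `peak_r`, `n_days`.
#' @export
gpp_lag_profile <- function(rs_daily, gpp_daily, max_lag = 45,
                            min_pairs = 10) {
  gcol <- intersect(c("gpp_gC_m2_d", "gpp"), names(gpp_daily))[1]
  if (is.na(gcol)) stop("gpp_daily needs a gpp_gC_m2_d or gpp column")
  rcol <- intersect(c("rs", "day_mean_rs"), names(rs_daily))[1]
  dates <- seq(min(c(rs_daily$date, gpp_daily$date)),
               max(c(rs_daily$date, gpp_daily$date)), by = "day")
  rs <- rs_daily[[rcol]][match(dates, rs_daily$date)]
  gpp <- gpp_daily[[gcol]][match(dates, gpp_daily$date)]
  lags <- 0:max_lag
  r <- vapply(lags, function(l) {
    if (l >= length(dates)) return(NA_real_)
    a <- rs[(l + 1):length(dates)]
    b <- gpp[1:(length(dates) - l)]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < min_pairs) return(NA_real_)
    if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) return(NA_real_)
    stats::cor(a[ok], b[ok])
  }, numeric(1))
  peak <- if (all(is.na(r))) NA_integer_ else which.max(r)  # earliest tie
  list(lags = lags, r_by_lag = r,
       peak_lag = if (is.na(peak)) NA_integer_ else lags[peak],
       peak_r = if (is.na(peak)) NA_real_ else r[peak],
       n_days = sum(is.finite(rs) & is.finite(gpp)))
}

#' Period-specific SMA of daily Rs against same-day GPP
#'
#' Fits the daytime and the nighttime daily mean Rs against daily GPP with
#' SMA, for comparing whether the nighttime flux tracks photosynthesis more
#' tightly (steeper slope or higher elevation) than the daytime flux.
#'
#' @param daily output of [daily_means()] with `diel_date`.
#' @param gpp_daily daily GPP table (`date`, `gpp_gC_m2_d`).
#' @return list with elements `day` and `night`, each an [sma_fit()]
#'   result.
#' @export
rs_gpp_sma <- function(daily, gpp_daily) {
  gcol <- intersect(c("gpp_gC_m2_d", "gpp"), names(gpp_daily))[1]
  gpp <- gpp_daily[[gcol]][match(daily$diel_date, gpp_daily$date)]
  list(day = sma_fit(gpp, daily$day_mean_rs),
       night = sma_fit(gpp, daily$night_mean_rs))
}
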