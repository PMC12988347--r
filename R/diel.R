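# Diel analysis: paired daily day/night means, significance of the diel
# difference, exponential temperature-response fits (Q10), and temperature
# adjustment of fluxes to the site mean soil temperature.

#' Daily paired day/night means
#'
#' One row per `diel_date` holding the mean daytime and nighttime Rs, Ts and
#' (when present) SWC, with the contributing hour counts. Dates missing
#' either period are dropped: the diel comparison is paired by construction.
#'
#' @param series labelled, QC'd hourly series.
#' @return data.frame with columns `diel_date`, `day_mean_*`,
#'   `night_mean_*`, `n_day_hours`, `n_night_hours`.
#' @export
daily_means <- function(series) {
  vars <- intersect(c("rs", "ts", "swc"), names(series))
  out <- NULL
  for (p in c("day", "night")) {
    s <- series[series$period == p, , drop = FALSE]
    agg <- stats::aggregate(s[vars], by = list(diel_date = s$diel_date),
                            FUN = mean, na.rm = TRUE)
    names(agg)[-1] <- paste0(p, "_mean_", vars)
    cnt <- stats::aggregate(list(n = s$rs),
                            by = list(diel_date = s$diel_date), FUN = length)
    names(cnt)[2] <- paste0("n_", p, "_hours")
    agg <- merge(agg, cnt, by = "diel_date")
    out <- if (is.null(out)) agg else merge(out, agg, by = "diel_date")
  }
  out <- out[order(out$diel_date), , drop = FALSE]
  rownames(out) <- NULL
  if ("site_id" %in% names(series)) out$site_id <- series$site_id[1]
  out
}

#' Paired test of the diel (night minus day) difference
#'
#' Two-sided paired Student's t-test of nightly minus daytime daily means
#' across diel dates, for Rs, Ts or SWC. The percent difference for Rs is
#' 100 * delta / mean(daytime mean).
#'
#' @param daily output of [daily_means()].
#' @param variable one of "rs", "ts", "swc".
#' @param alpha significance level for classification (default 0.05).
#' @param min_days fewer paired days than this yields class "ns" with a
#'   `low_n` flag instead of a test (default 5).
#' @param paired set `FALSE` for an unpaired Welch test.
#' @return list: `variable`, `delta` (night - day mean), `sem`,
#'   `percent_delta`, `t_stat`, `p_value`, `n_days`, `class`
#'   ("pos"/"neg"/"ns"), `low_n`.
#' @export
diel_test <- function(daily, variable = "rs", alpha = 0.05, min_days = 5,
                      paired = TRUE) {
  d <- daily[[paste0("day_mean_", variable)]]
  n <- daily[[paste0("night_mean_", variable)]]
  ok <- is.finite(d) & is.finite(n)
  d <- d[ok]; n <- n[ok]
  diff <- n - d
  out <- list(variable = variable, delta = mean(diff),
              sem = stats::sd(diff) / sqrt(length(diff)),
              percent_delta = 100 * mean(diff) / mean(d),
              n_days = length(diff), low_n = FALSE)
  if (length(diff) < min_days) {
    out$t_stat <- NA_real_; out$p_value <- NA_real_
    out$class <- "ns"; out$low_n <- TRUE
    return(out)
  }
  if (stats::sd(diff) == 0) {
    # degenerate: constant shift (or identical series)
    out$t_stat <- if (mean(diff) == 0) 0 else Inf * sign(mean(diff))
    out$p_value <- if (mean(diff) == 0) 1 else 0
  } else {
    tt <- if (paired) stats::t.test(n, d, paired = TRUE) else
      stats::t.test(n, d)
    out$t_stat <- unname(tt$statistic)
    out$p_value <- tt$p.value
  }
  out$class <- if (out$p_value < alpha && out$delta > 0) "pos"
    else if (out$p_value < alpha && out$delta < 0) "neg" else "ns"
  out
}

#' Fit the exponential temperature response Rs = Rs0 * exp(beta * Ts)
#'
#' Default estimator is ordinary least squares on the log scale,
#' ln Rs = ln Rs0 + beta Ts (closed form, robust under multiplicative
#' noise). `method = "nls"` refits on the original scale by nonlinear least
#' squares initialised from the log fit. Q10 = exp(10 beta) exactly.
#'
#' @param series hourly series with `rs` (> 0) and `ts`.
#' @param period optional "day"/"night" to subset a labelled series; NULL
#'   fits all rows.
#' @param method "log_ols" (default) or "nls".
#' @param min_hours minimum number of hours required (default 30).
#' @return list: `period`, `rs0`, `beta`, `q10`, `se_beta`, `r2` (on the
#'   fitting scale), `n_hours`, `fit_method`.
#' @export
fit_temp_response <- function(series, period = NULL, method = "log_ols",
                              min_hours = 30) {
  s <- series
  if (!is.null(period)) s <- s[s$period == period, , drop = FALSE]
  ok <- is.finite(s$rs) & is.finite(s$ts) & s$rs > 0
  s <- s[ok, , drop = FALSE]
  if (nrow(s) < min_hours) {
    stop("too few hours (", nrow(s), ") to fit temperature response")
  }
  if (stats::sd(s$ts) == 0) stop("temperature range too small")
  fit <- stats::lm(log(rs) ~ ts, data = s)
  cf <- stats::coef(fit)
  beta <- unname(cf[2]); rs0 <- exp(unname(cf[1]))
  # suppress the benign "essentially perfect fit" note on noiseless data
  sm <- suppressWarnings(summary(fit))
  se_beta <- sm$coefficients[2, 2]
  r2 <- sm$r.squared
  tag <- "log_ols"
  if (method == "nls") {
    nfit <- tryCatch(
      stats::nls(rs ~ a * exp(b * ts), data = s,
                 start = list(a = rs0, b = beta),
                 control = stats::nls.control(maxiter = 200,
                                              warnOnly = TRUE)),
      error = function(e) NULL)
    if (!is.null(nfit)) {
      cf <- stats::coef(nfit)
      rs0 <- unname(cf["a"]); beta <- unname(cf["b"])
      se_beta <- summary(nfit)$coefficients["b", 2]
      r2 <- 1 - sum(stats::resid(nfit)^2) / sum((s$rs - mean(s$rs))^2)
      tag <- "nls"
    }
  }
  list(period = if (is.null(period)) "all" else period,
       rs0 = rs0, beta = beta, q10 = exp(10 * beta),
       se_beta = se_beta, r2 = r2, n_hours = nrow(s), fit_method = tag)
}

#' Site mean soil temperature
#'
#' Mean over all hourly soil-temperature records of the (season-filtered)
#' series; the reference temperature for [adjust_to_mean_temp()].
#'
#' @param series hourly series with a `ts` column.
#' @export
site_mean_ts <- function(series) mean(series$ts, na.rm = TRUE)

#' Temperature-adjust daily fluxes to the site mean temperature
#'
#' Each period's daily mean Rs is rescaled to the common reference
#' temperature with its own period's Q10:
#' Rs_adj = Rs * Q10 ^ ((Tbar - Ts) / 10). When a period's daily mean Ts
#' equals the reference the flux is unchanged.
#'
#' @param daily output of [daily_means()].
#' @param day_fit,night_fit [fit_temp_response()] results for the two
#'   periods.
#' @param ref_ts reference temperature Tbar (site mean Ts), degrees C.
#' @return `daily` with added `day_rs_adj`, `night_rs_adj`, `ref_ts`.
#' @export
adjust_to_mean_temp <- function(daily, day_fit, night_fit, ref_ts) {
  if (is.null(day_fit) || is.null(night_fit)) {
    stop("both day and night temperature-response fits are required")
  }
  daily$day_rs_adj <- daily$day_mean_rs *
    day_fit$q10^((ref_ts - daily$day_mean_ts) / 10)
  daily$night_rs_adj <- daily$night_mean_rs *
    night_fit$q10^((ref_ts - daily$night_mean_ts) / 10)
  daily$ref_ts <- ref_ts
  daily
}
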