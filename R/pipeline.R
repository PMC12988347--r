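# End-to-end orchestration: per-site QC -> partition -> diel summary ->
# temperature fits -> adjustment -> nighttime bias, then cross-site
# synthesis (SMA, significance classes, forest-type summaries) and a run
# manifest recording every threshold in force.

#' Default forest-type areas
#'
#' Approximate global areas (m2) of the five IGBP forest classes, of the
#' magnitude derived from coarse land-cover products (MCD12C1-like);
#' configuration constants, not downloaded data. Override freely.
#' @export
default_forest_areas <- function() {
  c(DBF = 1.7e12, EBF = 1.2e13, DNF = 1.3e12, ENF = 3.0e12, MF = 7.0e12)
}

#' Analyse one site end-to-end
#'
#' Labels hours, selects the season, runs the QC cascade, computes daily
#' paired means and the diel tests, fits day and night temperature
#' responses, temperature-adjusts daily fluxes, and measures the nighttime
#' prediction bias from the daytime fit.
#'
#' @param series hourly series (e.g. from [aggregate_hourly()] or
#'   [generate_site()]).
#' @param meta site metadata.
#' @param season season selector (default "summer").
#' @param alpha significance level.
#' @param min_fit_hours floor for the temperature fits.
#' @return list: `site_id`, `qc_report`, `daily`, `diel` (per-variable
#'   tests), `fits` (day/night), `adjusted`, `adjusted_test`, `bias`,
#'   `mean_ts`, `excluded` (FALSE, or a reason string).
#' @export
analyze_site <- function(series, meta, season = "summer", alpha = 0.05,
                         min_fit_hours = 30) {
  res <- list(site_id = meta$site_id, igbp = meta$igbp, excluded = FALSE)
  out <- tryCatch({
    lab <- label_hours(series, meta)
    lab <- season_filter(lab, meta, season)
    qc <- qc_cascade(lab)
    res$qc_report <- qc$report
    s <- qc$series
    if (nrow(s) == 0) stop("no data after QC")
    res$mean_ts <- site_mean_ts(s)
    res$daily <- daily_means(s)
    res$diel <- list(
      rs = diel_test(res$daily, "rs", alpha = alpha),
      ts = diel_test(res$daily, "ts", alpha = alpha))
    if ("swc" %in% names(s)) {
      res$diel$swc <- diel_test(res$daily, "swc", alpha = alpha)
    }
    res$fits <- list(
      day = fit_temp_response(s, "day", min_hours = min_fit_hours),
      night = fit_temp_response(s, "night", min_hours = min_fit_hours))
    res$adjusted <- adjust_to_mean_temp(res$daily, res$fits$day,
                                        res$fits$night, res$mean_ts)
    adj <- res$adjusted
    adj$day_mean_rs <- adj$day_rs_adj
    adj$night_mean_rs <- adj$night_rs_adj
    res$adjusted_test <- diel_test(adj, "rs", alpha = alpha)
    pairs <- predict_night_from_day(s, res$fits$day)
    res$bias <- bias_test(pairs, min_hours = min_fit_hours)
    res
  }, error = function(e) {
    res$excluded <- conditionMessage(e)
    res
  })
  out
}

#' Run the pipeline over a batch of sites
#'
#' @param sites list of lists, each with `series` and `meta` (the shape
#'   returned by [generate_site()]).
#' @param season,alpha,min_fit_hours as in [analyze_site()].
#' @param areas forest-type areas (m2) for the global extrapolation.
#' @return list: `sites` (per-site results), `site_table` (one row per
#'   included site), `cross` (day-night SMA, class counts, per-forest-type
#'   summary, global extrapolation), `manifest`.
#' @export
run_pipeline <- function(sites, season = "summer", alpha = 0.05,
                         min_fit_hours = 30,
                         areas = default_forest_areas()) {
  if (length(sites) == 0) stop("empty site list")
  per_site <- lapply(sites, function(st)
    analyze_site(st$series, st$meta, season = season, alpha = alpha,
                 min_fit_hours = min_fit_hours))
  names(per_site) <- vapply(per_site, `[[`, "", "site_id")
  ok <- vapply(per_site, function(r) isFALSE(r$excluded), TRUE)
  rows <- lapply(per_site[ok], function(r) {
    data.frame(site_id = r$site_id, igbp = r$igbp,
               mean_ts = r$mean_ts,
               day_mean_rs = mean(r$daily$day_mean_rs),
               night_mean_rs = mean(r$daily$night_mean_rs),
               delta_rs = r$diel$rs$delta,
               delta_rs_sem = r$diel$rs$sem,
               percent_delta_rs = r$diel$rs$percent_delta,
               delta_ts = r$diel$ts$delta,
               class = r$diel$rs$class,
               q10_day = r$fits$day$q10, q10_night = r$fits$night$q10,
               bias_pct = r$bias$bias_pct,
               bias_flux_gap = r$bias$obs_night_mean -
                 r$bias$pred_night_mean)
  })
  site_table <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  cross <- list()
  if (!is.null(site_table) && nrow(site_table) >= 3) {
    cross$sma <- day_night_sma(site_table)
    cross$class_counts <- table(factor(site_table$class,
                                       levels = c("pos", "neg", "ns")))
    cross$delta_rs_mean <- mean(site_table$delta_rs)
    cross$delta_rs_sem <- stats::sd(site_table$delta_rs) /
      sqrt(nrow(site_table))
    cross$percent_delta_rs_mean <- mean(site_table$percent_delta_rs)
    cross$percent_delta_rs_sem <- stats::sd(site_table$percent_delta_rs) /
      sqrt(nrow(site_table))
    cross$by_forest_type <- summarize_by_forest_type(site_table)
    gaps <- tapply(site_table$bias_flux_gap, site_table$igbp, mean)
    gaps <- gaps[names(gaps) %in% names(areas)]
    cross$global <- extrapolate_global(stats::setNames(as.numeric(gaps),
                                                       names(gaps)), areas)
  }
  manifest <- list(season = season, alpha = alpha,
                   min_fit_hours = min_fit_hours,
                   min_day_hours = 3, min_night_hours = 3,
                   min_days_month = 10, depth_target_cm = 5,
                   quantile_type = 7, pairing = "sunset_anchored",
                   estimator = "log_ols",
                   excluded = lapply(per_site[!ok], `[[`, "excluded"))
  list(sites = per_site, site_table = site_table, cross = cross,
       manifest = manifest)
}

#' Per-forest-type summary of site-level results
#'
#' Unweighted site means with SEM for each IGBP class present, ordered by
#' ascending class mean soil temperature. Classes with a single site report
#' `NA` SEM.
#'
#' @param site_table the `site_table` from [run_pipeline()] (needs `igbp`,
#'   `mean_ts`, `delta_rs`, `percent_delta_rs`).
#' @return data.frame: `igbp`, `n_sites`, `mean_ts`, `delta_rs_mean`,
#'   `delta_rs_sem`, `percent_delta_rs_mean`.
#' @export
summarize_by_forest_type <- function(site_table) {
  sem <- function(x) if (length(x) < 2) NA_real_ else
    stats::sd(x) / sqrt(length(x))
  cls <- split(site_table, site_table$igbp)
  out <- do.call(rbind, lapply(cls, function(s) {
    data.frame(igbp = s$igbp[1], n_sites = nrow(s),
               mean_ts = mean(s$mean_ts),
               delta_rs_mean = mean(s$delta_rs),
               delta_rs_sem = sem(s$delta_rs),
               percent_delta_rs_mean = mean(s$percent_delta_rs))
  }))
  out <- out[order(out$mean_ts), , drop = FALSE]
  rownames(out) <- NULL
  out
}
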