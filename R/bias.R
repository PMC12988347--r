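# Bias of extrapolating nighttime fluxes from daytime temperature
# relationships, its attribution to root vs heterotrophic components, and
# the rough global (forest-type) carbon consequence.

#' Predict nighttime fluxes from a daytime temperature fit
#'
#' Applies the daytime parameters to nighttime soil temperatures:
#' pred(t) = rs0_day * exp(beta_day * ts(t)) for every night hour.
#'
#' @param series labelled hourly series.
#' @param day_fit a [fit_temp_response()] result for the daytime period.
#' @param target column to treat as the observed flux (default "rs").
#' @return data.frame of night hours with `obs` and `pred` columns.
#' @export
predict_night_from_day <- function(series, day_fit, target = "rs") {
  night <- series[series$period == "night", , drop = FALSE]
  ok <- is.finite(night[[target]]) & is.finite(night$ts)
  night <- night[ok, , drop = FALSE]
  if (nrow(night) == 0) stop("no night hours to predict")
  data.frame(diel_date = night$diel_date, ts = night$ts,
             obs = night[[target]],
             pred = day_fit$rs0 * exp(day_fit$beta * night$ts))
}

#' Bias of predicted versus observed nighttime fluxes
#'
#' Bias% = 100 * (mean(pred) - mean(obs)) / mean(obs); negative values mean
#' the daytime relationship underestimates the nighttime flux. Significance
#' from a two-sided paired t-test on the hourly (pred - obs) differences.
#'
#' @param pairs data.frame with `pred` and `obs` (from
#'   [predict_night_from_day()]).
#' @param min_hours minimum paired hours (default 30).
#' @return list: `pred_night_mean`, `obs_night_mean`, `bias_pct`,
#'   `bias_flux` (pred - obs means, umol m-2 s-1), `p_value`, `n_hours`.
#' @export
bias_test <- function(pairs, min_hours = 30) {
  if (nrow(pairs) < min_hours) {
    stop("fewer than ", min_hours, " paired night hours")
  }
  pm <- mean(pairs$pred); om <- mean(pairs$obs)
  diff <- pairs$pred - pairs$obs
  p <- if (stats::sd(diff) == 0) {
    if (mean(diff) == 0) 1 else 0
  } else {
    stats::t.test(pairs$pred, pairs$obs, paired = TRUE)$p.value
  }
  list(pred_night_mean = pm, obs_night_mean = om,
       bias_pct = 100 * (pm - om) / om,
       bias_flux = pm - om, p_value = p, n_hours = nrow(pairs))
}

#' Attribute the nighttime prediction bias to flux components
#'
#' Requires an `rh` column (e.g. trenched-plot heterotrophic respiration);
#' root respiration is the difference rroot = rs - rh, with negative values
#' dropped (counted). Each component gets its own daytime temperature fit
#' and nighttime bias; the root contribution is the root bias flux as a
#' percentage of the total bias flux.
#'
#' @param series labelled hourly series with `rs` and `rh` columns.
#' @param min_hours per-fit floor passed through.
#' @param max_negative_frac sites with more than this fraction of negative
#'   rroot hours are rejected (default 0.2).
#' @return list with per-target bias results (`rs`, `rroot`, `rh`),
#'   `bias_flux_*` fields, `root_contribution_pct` (NA when the total bias
#'   flux is ~0) and `n_negative_rroot`.
#' @export
attribute_components <- function(series, min_hours = 30,
                                 max_negative_frac = 0.2) {
  if (!"rh" %in% names(series)) stop("rh column required for attribution")
  series$rroot <- series$rs - series$rh
  neg <- series$rroot < 0
  if (mean(neg, na.rm = TRUE) > max_negative_frac) {
    stop("more than ", 100 * max_negative_frac,
         "% of hours have negative rroot; site excluded from attribution")
  }
  series <- series[!neg | is.na(neg), , drop = FALSE]
  out <- list(n_negative_rroot = sum(neg, na.rm = TRUE))
  for (target in c("rs", "rroot", "rh")) {
    s <- series
    s$rs_target <- s[[target]]
    fit <- fit_temp_response(
      within(s, rs <- rs_target), period = "day", min_hours = min_hours)
    pairs <- predict_night_from_day(s, fit, target = target)
    out[[target]] <- bias_test(pairs, min_hours = min_hours)
    out[[paste0("bias_flux_", target)]] <- out[[target]]$bias_flux
  }
  total <- out$bias_flux_rs
  out$root_contribution_pct <- if (abs(total) < 1e-12) NA_real_ else
    100 * out$bias_flux_rroot / total
  out
}

#' Scale nighttime flux-prediction gaps to forest-type carbon totals
#'
#' carbon_total (Pg C) = gap (umol CO2 m-2 s-1) x area (m2) x night seconds
#' x 12 g C mol-1 x 1e-6 mol umol-1 x 1e-15 Pg g-1. The gap is observed
#' minus predicted nighttime flux, so underestimation yields a positive
#' missed-carbon total.
#'
#' @param gaps named numeric vector (or data.frame with `igbp`,
#'   `mean_flux_gap`) of per-class mean flux gaps, umol m-2 s-1.
#' @param areas named numeric vector of class areas, m2.
#' @param night_seconds seconds of nighttime in the season considered
#'   (default 92 nights of 12 h).
#' @return data.frame: `igbp`, `mean_flux_gap`, `area_m2`, `night_seconds`,
#'   `carbon_total_PgC`.
#' @export
extrapolate_global <- function(gaps, areas,
                               night_seconds = 92 * 12 * 3600) {
  if (is.data.frame(gaps)) {
    g <- stats::setNames(gaps$mean_flux_gap, gaps$igbp)
  } else g <- gaps
  classes <- names(g)
  if (is.null(classes) || !all(classes %in% names(areas))) {
    stop("every flux-gap class needs a matching area")
  }
  a <- areas[classes]
  data.frame(igbp = classes,
             mean_flux_gap = unname(g),
             area_m2 = unname(a),
             night_seconds = night_seconds,
             carbon_total_PgC = unname(g * a * night_seconds *
                                         12 * 1e-6 * 1e-15),
             row.names = NULL)
}
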