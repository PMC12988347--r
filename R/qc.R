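# Quality-control cascade for hourly labelled chamber series. The rules run
# in a fixed order -- treatments, non-positive/outlier fluxes, daily
# coverage, monthly coverage -- and each reports what it removed.

#' Drop rows from experimental treatments
#'
#' Keeps only ambient/control rows (treatment in "none", "control",
#' "ambient", or NA). A missing treatment column keeps everything.
#'
#' @param series hourly series.
#' @return filtered series.
#' @export
drop_treatments <- function(series) {
  if (!"treatment" %in% names(series)) return(series)
  keep <- is.na(series$treatment) |
    tolower(series$treatment) %in% c("none", "control", "ambient", "")
  series[keep, , drop = FALSE]
}

#' Remove non-positive fluxes and Tukey-fence outliers
#'
#' Non-positive Rs values are dropped first; Tukey fences
#' \[Q1 - 1.5 IQR, Q3 + 1.5 IQR\] are then computed on the remaining values
#' of the dataset at hand (quantiles by linear interpolation, type 7) and
#' rows outside the fences are dropped. With zero IQR the fences collapse to
#' the common value and nothing is removed.
#'
#' @param series hourly series with an `rs` column.
#' @return filtered series.
#' @export
drop_nonpositive_and_outliers <- function(series) {
  ok <- is.finite(series$rs) & series$rs > 0
  series <- series[ok, , drop = FALSE]
  if (nrow(series) < 4) {
    stop("fewer than 4 positive flux values; site excluded")
  }
  q <- stats::quantile(series$rs, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[2] + 1.5 * iqr
  series[series$rs >= lo & series$rs <= hi, , drop = FALSE]
}

# diel_dates passing the >=3 valid hours in each period rule
covered_dates <- function(series) {
  valid <- is.finite(series$rs) & is.finite(series$ts)
  s <- series[valid, , drop = FALSE]
  tab <- table(factor(s$period, levels = c("day", "night")),
               as.character(s$diel_date))
  colnames(tab)[tab["day", ] >= 3 & tab["night", ] >= 3]
}

#' Keep only diel dates with enough coverage in both periods
#'
#' A diel date survives only with at least 3 daytime and 3 nighttime hours
#' carrying valid Rs and Ts.
#'
#' @param series labelled hourly series (see [label_hours()]).
#' @return filtered series.
#' @export
enforce_daily_coverage <- function(series) {
  keep <- as.character(series$diel_date) %in% covered_dates(series)
  series[keep, , drop = FALSE]
}

#' Keep only months with enough measured days
#'
#' Calendar months (of `diel_date`) with fewer than `min_days` surviving
#' diel dates are removed.
#'
#' @param series series already passed through [enforce_daily_coverage()].
#' @param min_days minimum days per month (default 10).
#' @return filtered series.
#' @export
enforce_monthly_coverage <- function(series, min_days = 10) {
  month <- strftime(series$diel_date, "%Y-%m")
  days_per_month <- tapply(as.character(series$diel_date), month,
                           function(d) length(unique(d)))
  keep_months <- names(days_per_month)[days_per_month >= min_days]
  series[month %in% keep_months, , drop = FALSE]
}

#' Run the full QC cascade and report per-rule removals
#'
#' Applies, in order: treatment exclusion, non-positive/outlier removal,
#' daily coverage, monthly coverage. The cascade is idempotent: running it
#' on its own output removes nothing further.
#'
#' @param series labelled hourly series.
#' @param min_days_month minimum surviving days per month.
#' @return list with `series` (filtered) and `report` (data.frame of rule,
#'   rows removed, rows remaining).
#' @export
qc_cascade <- function(series, min_days_month = 10) {
  n0 <- nrow(series)
  steps <- list(
    treatments = drop_treatments,
    nonpositive_outliers = drop_nonpositive_and_outliers,
    daily_coverage = enforce_daily_coverage,
    monthly_coverage = function(s) enforce_monthly_coverage(s,
                                                            min_days_month))
  removed <- integer(length(steps))
  remaining <- integer(length(steps))
  for (i in seq_along(steps)) {
    before <- nrow(series)
    series <- steps[[i]](series)
    removed[i] <- before - nrow(series)
    remaining[i] <- nrow(series)
  }
  report <- data.frame(rule = names(steps), removed = removed,
                       remaining = remaining)
  attr(report, "initial") <- n0
  list(series = series, report = report)
}
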