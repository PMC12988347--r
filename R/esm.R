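# Evaluation of hourly land-model output (e.g. the ECA and RD nutrient
# configurations of a land-surface model) for diel fidelity of simulated
# soil, root and heterotrophic respiration.

#' Label model hours day/night by the GPP-zero rule
#'
#' Night is any hour whose simulated GPP is (numerically) zero; a small
#' epsilon absorbs floating-point storage of zeros. `diel_date` follows the
#' same sunset-anchored convention as [label_hours()]: night hours in the
#' early morning belong to the previous date's night.
#'
#' @param series hourly model series with a `gpp` column (from
#'   [read_model_output()] or [generate_site()]).
#' @param eps threshold below which GPP counts as zero (default 1e-6
#'   umol m-2 s-1).
#' @return series with `period` and `diel_date` columns.
#' @export
gpp_day_night_split <- function(series, eps = 1e-6) {
  if (!"gpp" %in% names(series)) stop("gpp column required")
  series <- ensure_date_hour(series)
  series$period <- ifelse(series$gpp <= eps, "night", "day")
  series$diel_date <- series$date
  before_noon_night <- series$period == "night" & series$hour < 12
  series$diel_date[before_noon_night] <-
    series$date[before_noon_night] - 1L
  series
}

#' Multi-year day/night means of simulated respiration components
#'
#' Period means over the whole series for each target, with the percent by
#' which the nighttime mean falls below the daytime mean:
#' pct_night_lower = 100 * (day - night) / day.
#'
#' @param series labelled model series (see [gpp_day_night_split()]).
#' @param targets flux columns to summarise (default rs, rroot, rh).
#' @param config_label free label carried through (e.g. "ECA-like").
#' @return data.frame: one row per target with `day_mean`, `night_mean`,
#'   `pct_night_lower`, plus `site_id` and `config_label`.
#' @export
model_diel_summary <- function(series, targets = c("rs", "rroot", "rh"),
                               config_label = "model") {
  targets <- intersect(targets, names(series))
  if (!length(targets)) stop("none of the target columns are present")
  rows <- lapply(targets, function(v) {
    dm <- mean(series[[v]][series$period == "day"], na.rm = TRUE)
    nm <- mean(series[[v]][series$period == "night"], na.rm = TRUE)
    data.frame(target = v, day_mean = dm, night_mean = nm,
               pct_night_lower = 100 * (dm - nm) / dm)
  })
  out <- do.call(rbind, rows)
  out$site_id <- if ("site_id" %in% names(series)) series$site_id[1] else NA
  out$config_label <- config_label
  out
}

#' Cross-site SMA of simulated night versus day means
#'
#' @param summaries rbind of [model_diel_summary()] rows across sites.
#' @param target flux component to compare ("rs", "rroot" or "rh").
#' @return [sma_fit()] of night on day site means.
#' @export
model_sma <- function(summaries, target = "rs") {
  s <- summaries[summaries$target == target, , drop = FALSE]
  if (nrow(s) < 3) stop("need at least 3 sites for SMA")
  sma_fit(s$day_mean, s$night_mean)
}
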