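# Ingestion of chamber-flux CSVs, site metadata YAML, daily GPP tables and
# hourly land-model output into the package's common hourly data model.

IGBP_FOREST <- c("DBF", "EBF", "DNF", "ENF", "MF")

#' Site metadata record
#'
#' @param site_id identifier string.
#' @param lat,lon decimal degrees.
#' @param utc_offset hours of site standard time minus UTC.
#' @param igbp one of the five IGBP forest classes: DBF, EBF, DNF, ENF, MF.
#' @return a `site_meta` list; `hemisphere` is derived from the latitude sign.
#' @export
make_site_meta <- function(site_id, lat, lon, utc_offset, igbp) {
  if (abs(lat) > 90) stop("latitude out of range: ", lat)
  igbp <- toupper(igbp)
  if (!igbp %in% IGBP_FOREST) {
    stop("igbp must be one of ", paste(IGBP_FOREST, collapse = ", "))
  }
  structure(list(site_id = site_id, lat = lat, lon = lon,
                 utc_offset = utc_offset, igbp = igbp,
                 hemisphere = if (lat < 0) "S" else "N"),
            class = "site_meta")
}

#' Read site metadata from YAML
#'
#' @param path YAML file with fields `site_id, lat, lon, utc_offset, igbp`.
#' @return a [make_site_meta()] record.
#' @export
read_site_meta <- function(path) {
  m <- yaml::read_yaml(path)
  need <- c("site_id", "lat", "lon", "utc_offset", "igbp")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("metadata missing fields: ",
                         paste(miss, collapse = ", "))
  make_site_meta(m$site_id, m$lat, m$lon, m$utc_offset, m$igbp)
}

#' Read a chamber-flux CSV into sub-hourly records
#'
#' Expects at least `timestamp_iso`, `port` and `rs_umol_m2_s`, plus one or
#' more depth-suffixed temperature (`ts_C_<d>cm`) and water-content
#' (`swc_pct_<d>cm`) columns. Timestamps are interpreted as site standard
#' time. Rows are returned sorted by timestamp; unknown columns are kept.
#'
#' @param path CSV file path.
#' @param meta site metadata (attached as an attribute).
#' @return data.frame of sub-hourly records with parsed `timestamp`, `date`
#'   and `hour` columns and a `site_id` column.
#' @export
read_flux_table <- function(path, meta) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp_iso", "port", "rs_umol_m2_s")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("flux table missing required columns: ",
         paste(miss, collapse = ", "))
  }
  if (!any(grepl("^ts_C_[0-9]+cm$", names(raw)))) {
    stop("flux table has no soil-temperature column (ts_C_<depth>cm)")
  }
  raw$timestamp <- as.POSIXct(raw$timestamp_iso,
                              format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (anyNA(raw$timestamp)) stop("unparseable timestamps in ", path)
  raw <- raw[order(raw$timestamp), , drop = FALSE]
  raw$date <- as.Date(raw$timestamp, tz = "UTC")
  raw$hour <- as.integer(strftime(raw$timestamp, "%H", tz = "UTC"))
  raw$site_id <- meta$site_id
  rownames(raw) <- NULL
  attr(raw, "meta") <- meta
  raw
}

# Parse the depth (cm) out of names like ts_C_5cm / swc_pct_10cm.
depth_of <- function(cols) {
  as.numeric(sub(".*_([0-9]+)cm$", "\\1", cols))
}

#' Select the measurement depth nearest a target
#'
#' Keeps, for soil temperature and water content separately, the column whose
#' depth is nearest `target_cm`; ties go to the shallower depth. The chosen
#' columns are renamed `ts` / `swc` and the depths recorded in attributes
#' `depth_used_ts` / `depth_used_swc`.
#'
#' @param records sub-hourly records from [read_flux_table()].
#' @param target_cm target depth, cm (default 5, the layer that dominates
#'   the surface efflux signal).
#' @return records with canonical `ts` (and `swc` when present) columns.
#' @export
select_depth <- function(records, target_cm = 5) {
  pick <- function(cols) {
    d <- depth_of(cols)
    # order by distance to target, then shallower first
    cols[order(abs(d - target_cm), d)][1]
  }
  ts_cols <- grep("^ts_C_[0-9]+cm$", names(records), value = TRUE)
  if (!length(ts_cols)) stop("no soil-temperature depth columns present")
  ts_col <- pick(ts_cols)
  records$ts <- records[[ts_col]]
  attr(records, "depth_used_ts") <- depth_of(ts_col)
  swc_cols <- grep("^swc_pct_[0-9]+cm$", names(records), value = TRUE)
  if (length(swc_cols)) {
    swc_col <- pick(swc_cols)
    records$swc <- records[[swc_col]]
    attr(records, "depth_used_swc") <- depth_of(swc_col)
  }
  records$rs <- records$rs_umol_m2_s
  records
}

#' Aggregate sub-hourly records to an hourly series
#'
#' Within each clock hour \[h, h+1) each chamber port is averaged first, then
#' ports are averaged with equal weight. `n_subhourly` counts the raw records
#' contributing to the hour. Hours with no records are absent, never filled.
#' Aggregating an already-hourly single-port series is a no-op.
#'
#' @param records output of [select_depth()] (needs `rs`, `ts`, optionally
#'   `swc`, plus `date`, `hour`, `port`).
#' @return hourly data.frame: `site_id`, `timestamp`, `date`, `hour`, `rs`,
#'   `ts`, `swc` (if present), `n_subhourly`, `treatment` (if present; the
#'   first value in the hour).
#' @export
aggregate_hourly <- function(records) {
  if (nrow(records) == 0) {
    return(data.frame(site_id = character(), date = as.Date(character()),
                      hour = integer(), rs = numeric(), ts = numeric(),
                      n_subhourly = integer()))
  }
  vars <- intersect(c("rs", "ts", "swc"), names(records))
  port <- if ("port" %in% names(records)) records$port else
    rep("P1", nrow(records))
  port_means <- stats::aggregate(
    records[vars],
    by = list(date = records$date, hour = records$hour, port = port),
    FUN = mean, na.rm = TRUE)
  out <- stats::aggregate(
    port_means[vars],
    by = list(date = port_means$date, hour = port_means$hour),
    FUN = mean, na.rm = TRUE)
  cnt <- stats::aggregate(
    list(n_subhourly = records[[vars[1]]]),
    by = list(date = records$date, hour = records$hour), FUN = length)
  out <- merge(out, cnt, by = c("date", "hour"))
  if ("treatment" %in% names(records)) {
    first <- !duplicated(paste(records$date, records$hour))
    out <- merge(out, data.frame(date = records$date[first],
                                 hour = records$hour[first],
                                 treatment = records$treatment[first]),
                 by = c("date", "hour"))
  }
  out$site_id <- if (!is.null(attr(records, "meta"))) {
    attr(records, "meta")$site_id
  } else if ("site_id" %in% names(records)) records$site_id[1] else NA
  out$timestamp <- as.POSIXct(paste0(format(out$date), " ",
                                     sprintf("%02d", out$hour), ":00:00"),
                              tz = "UTC")
  out <- out[order(out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("meta", "depth_used_ts", "depth_used_swc")) {
    attr(out, a) <- attr(records, a)
  }
  out
}

#' Read an hourly land-model output table
#'
#' Schema: `timestamp_iso, rs, rroot, rh, gpp, ts_10cm` (fluxes in
#' umol m-2 s-1). When `rs` departs from `rroot + rh` by more than 5% on
#' average a consistency warning is raised; the rows are kept.
#'
#' @param path CSV path.
#' @param meta site metadata.
#' @return hourly data.frame with `timestamp`, `date`, `hour`, `rs`,
#'   `rroot`, `rh`, `gpp`, `ts`.
#' @export
read_model_output <- function(path, meta) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0) {
    return(data.frame(site_id = character(), date = as.Date(character()),
                      hour = integer(), rs = numeric(), rroot = numeric(),
                      rh = numeric(), gpp = numeric(), ts = numeric()))
  }
  need <- c("timestamp_iso", "rs", "rroot", "rh", "gpp")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("model output missing columns: ",
                         paste(miss, collapse = ", "))
  ts_col <- grep("^ts(_[0-9]+cm)?$", names(raw), value = TRUE)[1]
  if (is.na(ts_col)) stop("model output missing soil-temperature column")
  raw$timestamp <- as.POSIXct(raw$timestamp_iso,
                              format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  out <- data.frame(site_id = meta$site_id, timestamp = raw$timestamp,
                    date = as.Date(raw$timestamp, tz = "UTC"),
                    hour = as.integer(strftime(raw$timestamp, "%H",
                                               tz = "UTC")),
                    rs = raw$rs, rroot = raw$rroot, rh = raw$rh,
                    gpp = raw$gpp, ts = raw[[ts_col]])
  rel <- abs(out$rs - (out$rroot + out$rh)) /
    pmax(abs(out$rs), .Machine$double.eps)
  if (mean(rel, na.rm = TRUE) > 0.05) {
    warning("rs differs from rroot + rh by >5% on average in ", path)
  }
  out <- out[order(out$timestamp), , drop = FALSE]
  attr(out, "meta") <- meta
  out
}

#' Read a daily GPP table
#'
#' @param path CSV with columns `date, gpp_gC_m2_d`.
#' @return data.frame with `date` (Date) and `gpp_gC_m2_d`.
#' @export
read_gpp_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("date", "gpp_gC_m2_d"), names(raw))
  if (length(miss)) stop("GPP table missing columns: ",
                         paste(miss, collapse = ", "))
  raw$date <- as.Date(raw$date)
  raw
}
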