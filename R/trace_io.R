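#' Enumerated determinant levels for the cohort questionnaire
#'
#' The categorical exposure determinants recorded per child, with their full
#' level sets. "Not reported" is a first-class level wherever it occurs and is
#' never imputed: it enters the determinants model as its own coefficient.
#'
#' @return Named list mapping determinant column name to its character levels
#'   (first level = the modelling reference).
#' @export
determinant_levels <- function() {
  list(
    near_waste_burning    = c("No", "Yes"),
    near_construction     = c("No", "Yes"),
    help_with_cooking     = c("No", "Yes"),
    contact_with_animals  = c("No", "Yes"),
    commute_mode          = c("Walk", "Motorised", "Mixed mode", "No commute",
                              "Unclassified"),
    cooker_location       = c("Inside", "Outside", "Not reported"),
    cooker_type           = c("Electric", "Gas", "Gas and biomass",
                              "Coal or wood (biomass)", "Kerosene",
                              "Open fire and biomass", "Not reported"),
    lighting_use          = c("Electric only", "Candle", "Candle and other",
                              "Kerosene lamp and other",
                              "Rechargeable/solar lamp or torch",
                              "Not reported"),
    smoking_at_home       = c("No smokers", "Presence of smokers",
                              "Not reported"),
    gender                = c("Female", "Male"),
    near_busy_road        = c("Yes", "No", "Not reported"),
    school_ground_surface = c("Loose dirt", "Packed dirt", "Broken paving",
                              "Paved")
  )
}

# ---- timestamp helpers -------------------------------------------------

# Local clock time, DST-free study sites: ISO 8601 without offset, parsed in
# a fixed zone so arithmetic is linear.
parse_ts <- function(x, tz = "UTC") {
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = tz)
  sp <- is.na(out) & !is.na(x) & nzchar(x)
  if (any(sp)) {
    out[sp] <- as.POSIXct(x[sp], format = "%Y-%m-%d %H:%M:%S", tz = tz)
  }
  out
}

format_ts <- function(x) format(x, "%Y-%m-%dT%H:%M:%S")

# ---- trace reading -----------------------------------------------------

#' Read a raw sensor trace
#'
#' Reads a 1-s cadence trace CSV with columns
#' `timestamp,pm25,pm10,lat,lon`. Unparseable numeric fields become missing
#' and are counted (attribute `malformed`, also reported via `message()`);
#' PM values at or above the physical cap are treated as invalid readings and
#' blanked the same way. Rows whose timestamp cannot be parsed are dropped
#' and counted as malformed.
#'
#' @param path CSV file path.
#' @param config Configuration list, see [default_config()].
#' @return A `data.table` with columns `timestamp` (POSIXct), `pm25`, `pm10`,
#'   `lat`, `lon`; attribute `malformed` holds the malformed-field row count.
#' @export
read_trace <- function(path, config = default_config()) {
  if (!file.exists(path)) stop("trace file not found: ", path, call. = FALSE)
  raw <- data.table::fread(path, colClasses = "character",
                           na.strings = c("", "NA"), showProgress = FALSE)
  need <- c("timestamp", "pm25", "pm10", "lat", "lon")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("trace schema error: missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ts <- parse_ts(raw$timestamp, tz = config$io$tz)
  malformed <- 0L
  bad_ts <- is.na(ts)
  if (any(bad_ts)) {
    malformed <- malformed + sum(bad_ts)
    raw <- raw[!bad_ts]
    ts <- ts[!bad_ts]
  }
  num <- function(col) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- is.na(x) & !is.na(raw[[col]])
    malformed <<- malformed + sum(bad)
    x
  }
  out <- data.table::data.table(
    timestamp = ts, pm25 = num("pm25"), pm10 = num("pm10"),
    lat = num("lat"), lon = num("lon")
  )
  # physical cap: implausible readings are invalid, not truncated
  for (col in c("pm25", "pm10")) {
    x <- out[[col]]
    capped <- !is.na(x) & (x >= config$io$pm_cap | x < 0)
    if (any(capped)) data.table::set(out, which(capped), col, NA_real_)
  }
  if (nrow(out) > 1) {
    d <- diff(as.numeric(out$timestamp))
    if (any(d <= 0)) {
      row <- which(d <= 0)[1] + 1L
      stop(sprintf("trace data error: non-increasing timestamp at row %d (%s)",
                   row, format_ts(out$timestamp[row])), call. = FALSE)
    }
  }
  if (malformed > 0) {
    message(sprintf("read_trace: %d malformed field(s)/row(s) in %s",
                    malformed, basename(path)))
  }
  data.table::setattr(out, "malformed", malformed)
  out[]
}

#' Aggregate second-level samples to minute records
#'
#' Produces one record per calendar minute spanned by the trace (gap minutes
#' included, with zero valid samples). A minute's PM is valid when at least
#' `config$qc$minute_valid_min` samples carry finite PM; its GPS is valid
#' when at least one finite fix fell in the minute. Minutes are half-open
#' intervals `[minute_start, minute_start + 60 s)`.
#'
#' @param samples `data.table` from [read_trace()] (time-ordered).
#' @param config Configuration list.
#' @return `data.table` with columns `minute_start`, `pm25_mean`, `pm10_mean`,
#'   `lat`, `lon`, `n_samples_valid`, `pm_valid`, `gps_valid`.
#' @export
aggregate_minutes <- function(samples, config = default_config()) {
  empty <- data.table::data.table(
    minute_start = as.POSIXct(character(), tz = config$io$tz),
    pm25_mean = numeric(), pm10_mean = numeric(),
    lat = numeric(), lon = numeric(),
    n_samples_valid = integer(), pm_valid = logical(), gps_valid = logical()
  )
  if (is.null(samples) || nrow(samples) == 0) return(empty)
  s <- data.table::as.data.table(samples)
  s[, minute_start := trunc_minute(timestamp)]
  agg <- s[, .(
    pm25_mean = mean_or_na(pm25),
    pm10_mean = mean_or_na(pm10),
    lat = mean_or_na(lat),
    lon = mean_or_na(lon),
    n_samples_valid = sum(is.finite(pm25) | is.finite(pm10)),
    gps_valid = any(is.finite(lat) & is.finite(lon))
  ), by = minute_start]
  # full minute grid across the span, gaps included
  grid <- data.table::data.table(minute_start = seq(
    min(agg$minute_start), max(agg$minute_start), by = 60
  ))
  out <- agg[grid, on = "minute_start"]
  out[is.na(n_samples_valid), n_samples_valid := 0L]
  out[is.na(gps_valid), gps_valid := FALSE]
  out[, n_samples_valid := as.integer(n_samples_valid)]
  out[, pm_valid := n_samples_valid >= config$qc$minute_valid_min &
        is.finite(pm25_mean)]
  data.table::setcolorder(out, names(empty))
  out[]
}

trunc_minute <- function(x) {
  as.POSIXct(floor(as.numeric(x) / 60) * 60,
             origin = "1970-01-01", tz = attr(x, "tzone") %||% "UTC")
}

mean_or_na <- function(x) {
  x <- x[is.finite(x)]
  if (length(x)) mean(x) else NA_real_
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- other input tables ------------------------------------------------

#' Read the cohort/questionnaire table
#'
#' One row per child: `child_id,city_id,school_id,monitoring_start` plus the
#' determinant columns of [determinant_levels()]. Every categorical value
#' must come from its enumerated level set.
#'
#' @param path CSV path.
#' @param config Configuration list.
#' @return `data.table`, determinants as factors with full level sets.
#' @export
read_cohort <- function(path, config = default_config()) {
  dl <- determinant_levels()
  x <- data.table::fread(path, colClasses = "character",
                         na.strings = c("", "NA"), showProgress = FALSE)
  need <- c("child_id", "city_id", "school_id", names(dl))
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("cohort schema error: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (d in names(dl)) {
    bad <- !is.na(x[[d]]) & !(x[[d]] %in% dl[[d]])
    if (any(bad)) {
      stop(sprintf("cohort data error: invalid %s value '%s'",
                   d, x[[d]][which(bad)[1]]), call. = FALSE)
    }
    data.table::set(x, j = d, value = factor(x[[d]], levels = dl[[d]]))
  }
  if ("monitoring_start" %in% names(x)) {
    data.table::set(x, j = "monitoring_start",
                    value = parse_ts(x$monitoring_start, tz = config$io$tz))
  }
  x[]
}

#' Read a daily meteorology table
#' @param path CSV with columns `city_id,date,temp_c,rh_pct,wind_ms`.
#' @return `data.table` with `date` as `Date`.
#' @export
read_meteorology <- function(path) {
  x <- data.table::fread(path, showProgress = FALSE)
  need <- c("city_id", "date", "temp_c", "rh_pct", "wind_ms")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("meteorology schema error: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  x[, date := as.Date(date)]
  if (any(x$rh_pct < 0 | x$rh_pct > 100, na.rm = TRUE)) {
    stop("meteorology data error: rh_pct outside [0, 100]", call. = FALSE)
  }
  if (any(x$wind_ms < 0, na.rm = TRUE)) {
    stop("meteorology data error: negative wind_ms", call. = FALSE)
  }
  x[]
}

#' Read the daily-diary table
#'
#' At most one entry per child-day is allowed.
#'
#' @param path CSV with at least `child_id,date` and the per-day commute mode
#'   columns.
#' @return `data.table` with `date` as `Date`.
#' @export
read_diary <- function(path) {
  x <- data.table::fread(path, colClasses = "character",
                         na.strings = c("", "NA"), showProgress = FALSE)
  need <- c("child_id", "date")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("diary schema error: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  x[, date := as.Date(date)]
  dup <- x[, .N, by = .(child_id, date)][N > 1]
  if (nrow(dup)) {
    stop(sprintf("diary data error: duplicate entry for child %s on %s",
                 dup$child_id[1], dup$date[1]), call. = FALSE)
  }
  x[]
}

# ---- outputs -----------------------------------------------------------

#' Write pipeline output tables
#'
#' Writes each element of `tables` as `<name>.csv` under `out_dir`. Output is
#' deterministic: identical inputs produce byte-identical files. POSIXct
#' columns are serialised as ISO 8601; missing values as empty fields.
#'
#' @param tables Named list of data.frames.
#' @param out_dir Output directory (created if needed).
#' @param force Overwrite existing files? Default `FALSE` (refuses).
#' @return Character vector of file paths, invisibly.
#' @export
write_outputs <- function(tables, out_dir, force = FALSE) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) {
    stop("output I/O error: directory not writable: ", out_dir, call. = FALSE)
  }
  paths <- file.path(out_dir, paste0(names(tables), ".csv"))
  exists <- file.exists(paths)
  if (any(exists) && !force) {
    stop("output collision (use force = TRUE): ",
         paste(basename(paths[exists]), collapse = ", "), call. = FALSE)
  }
  for (i in seq_along(tables)) {
    tab <- data.table::as.data.table(tables[[i]])
    for (cn in names(tab)) {
      if (inherits(tab[[cn]], "POSIXct")) {
        data.table::set(tab, j = cn, value = format_ts(tab[[cn]]))
      }
    }
    data.table::fwrite(tab, paths[i], na = "", dateTimeAs = "write.csv")
  }
  invisible(paths)
}

#' Write a trace back to CSV (round-trip companion of [read_trace()])
#' @param samples Sensor sample table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(samples, path) {
  out <- data.table::as.data.table(samples)
  out <- out[, .(timestamp = format_ts(timestamp),
                 pm25 = round(pm25, 6), pm10 = round(pm10, 6),
                 lat = round(lat, 6), lon = round(lon, 6))]
  data.table::fwrite(out, path, na = "")
  invisible(path)
}
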