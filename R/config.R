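#' Default analysis configuration
#'
#' Returns the full set of tunable thresholds used across the pipeline as a
#' nested list. Every quantity that the QC filters, the microenvironment
#' tagger, the exposure summaries and the guideline comparison depend on is
#' held here, so a whole run is reproducible from one JSON document.
#'
#' Key defaults:
#' * `qc$minute_valid_min = 30`: a minute's PM mean is valid when at least 30
#'   of its (at most 60) one-second samples carry finite PM (50% rule).
#' * `qc$min_continuous_minutes = 1440`: inclusion requires *more than* 24 h
#'   of continuous valid data (strict inequality), tolerating internal
#'   invalid gaps of at most `qc$max_internal_gap_min` minutes inside a run.
#' * `qc$gps_gap_hours = 12`: children with more than 12 h of missing GPS are
#'   dropped from proportion-of-exposure outputs only.
#' * `tagger$home_radius_m = tagger$school_radius_m = 100`: geofence radii.
#' * `metrics$coverage_minutes = 1080`: 75% of a day must be valid for the
#'   day to contribute a daily mean.
#' * `metrics$who_pm25 = 15`, `metrics$who_pm10 = 45`: WHO 24-h guideline
#'   values in ug/m3; compliance uses strict `mean < threshold`.
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    io = list(
      pm_cap = 10000,          # ug/m3 hard physical cap; above -> invalid
      tz = "UTC"               # local clock time, DST-free sites
    ),
    qc = list(
      minute_valid_min = 30,
      max_internal_gap_min = 5,
      min_continuous_minutes = 1440,  # strict ">" applied
      count_clock_time = FALSE,       # valid-minute counting (see vignette)
      gps_gap_hours = 12
    ),
    tagger = list(
      home_radius_m = 100,
      school_radius_m = 100,
      commute_window_min = 120,
      carry_forward_limit = 60,
      grid_m = 50,
      overnight_hours = c(22, 5),   # 22:00-05:00, wrapping midnight
      school_hours = c(10, 14),     # 10:00-14:00 on school days
      min_window_fixes = 30
    ),
    metrics = list(
      coverage_minutes = 1080,
      who_pm25 = 15,
      who_pm10 = 45,
      ratio_pm10_min = 1,           # ug/m3 guard for per-minute ratios
      model_days = c("Monday", "Tuesday", "Wednesday", "Thursday")
    ),
    generator = default_generator_config()
  )
}

#' Read and validate a configuration JSON
#'
#' Unknown keys are rejected to catch typos; missing keys fall back to
#' [default_config()] values.
#'
#' @param path Path to a JSON file.
#' @return Validated nested configuration list.
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- modify_list_strict(default_config(), user, where = "config")
  validate_config(cfg)
  cfg
}

#' Write a configuration list as JSON
#' @param config Nested configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(namedvec_to_list(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

# jsonlite drops names of named atomic vectors (serialised as arrays);
# serialise them as objects instead so a round-trip preserves them
namedvec_to_list <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(x, namedvec_to_list))
  if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
  x
}

# recursive modifyList that refuses keys absent from the defaults
modify_list_strict <- function(base, user, where) {
  if (!is.list(user)) return(user)
  unknown <- setdiff(names(user), names(base))
  # generator city tables etc. are data-like lists; allow free-form below
  if (length(unknown) && !is.null(names(base))) {
    stop(sprintf("unknown config key(s) under %s: %s", where,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  for (k in names(user)) {
    bk <- base[[k]]
    uk <- user[[k]]
    base[[k]] <- if (is.atomic(bk) && !is.null(names(bk)) && is.list(uk)) {
      unlist(uk)  # named vector round-tripped through a JSON object
    } else if (is.list(bk) && !is.data.frame(bk) && !is.null(names(bk))) {
      modify_list_strict(bk, uk, paste(where, k, sep = "$"))
    } else {
      uk
    }
  }
  base
}

validate_config <- function(cfg) {
  q <- cfg$qc; t <- cfg$tagger; m <- cfg$metrics
  stopifnot(
    q$minute_valid_min >= 1, q$minute_valid_min <= 60,
    q$max_internal_gap_min >= 0,
    q$min_continuous_minutes > 0,
    q$gps_gap_hours > 0,
    t$home_radius_m > 0, t$school_radius_m > 0,
    t$commute_window_min > 0, t$carry_forward_limit >= 0, t$grid_m > 0,
    m$coverage_minutes >= 1, m$coverage_minutes <= 1440,
    m$who_pm25 > 0, m$who_pm10 > 0
  )
  validate_generator_config(cfg$generator)
  invisible(cfg)
}
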