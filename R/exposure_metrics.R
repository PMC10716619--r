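#' Daily mean exposures for one child
#'
#' Arithmetic means of PM-valid minutes per local calendar day. Days with
#' fewer than `config$metrics$coverage_minutes` valid minutes (75% of a day
#' by default) are omitted and counted in the `n_days_dropped` attribute.
#' Retained days are restricted to the `config$metrics$model_days` weekday
#' levels (Monday-Thursday): with a mid-morning Monday start and Friday
#' morning end, only full calendar days can meet the coverage rule.
#'
#' @param labeled Labelled (or plain) minute records for one child.
#' @param child_id Identifier carried into the output.
#' @param config Configuration list.
#' @return `data.table` `child_id, date, pm25_daily_mean, pm10_daily_mean,
#'   valid_minutes, day_of_week`.
#' @export
daily_means <- function(labeled, child_id = NA_character_,
                        config = default_config()) {
  m <- data.table::as.data.table(labeled)
  empty <- data.table::data.table(
    child_id = character(), date = as.Date(character()),
    pm25_daily_mean = numeric(), pm10_daily_mean = numeric(),
    valid_minutes = integer(), day_of_week = character()
  )
  if (nrow(m) == 0) return(empty)
  v <- m[pm_valid == TRUE]
  if (nrow(v) == 0) return(empty)
  d <- v[, .(
    pm25_daily_mean = mean(pm25_mean),
    pm10_daily_mean = mean_or_na(pm10_mean),
    valid_minutes = .N
  ), by = .(date = as.Date(minute_start))]
  d[, day_of_week := weekdays(date)]
  n_before <- nrow(d)
  d <- d[valid_minutes >= config$metrics$coverage_minutes &
           day_of_week %in% config$metrics$model_days]
  dropped <- n_before - nrow(d)
  if (dropped > 0) {
    message(sprintf("daily_means: %d day(s) below coverage/day-of-week rule%s",
                    dropped,
                    if (is.na(child_id)) "" else paste0(" for ", child_id)))
  }
  d[, child_id := child_id]
  data.table::setcolorder(d, names(empty))
  data.table::setattr(d, "n_days_dropped", dropped)
  d[]
}

#' Per-microenvironment exposure summary for one child
#'
#' For each label with at least one minute: mean/median PM2.5 over PM-valid
#' minutes, mean per-minute PM2.5:PM10 ratio (minutes with PM10 below
#' `ratio_pm10_min` excluded from the ratio), the ratio of means (sensitivity
#' companion), minute count, and the proportions of time and of total
#' exposure. Proportions are computed over labelled (non-`unknown`) minutes;
#' they are set missing when `gps_gap_over_12h` is `TRUE`, which removes the
#' child from proportion analyses while keeping the means.
#'
#' @param labeled Output of [tag_minutes()].
#' @param child_id Identifier carried into the output.
#' @param gps_gap_over_12h Flag from [validity_report()].
#' @param config Configuration list.
#' @return `data.table` `child_id, label, pm25_mean, pm25_median, ratio_mean,
#'   ratio_of_means, minutes, time_proportion, exposure_proportion`.
#' @export
microenv_summaries <- function(labeled, child_id = NA_character_,
                               gps_gap_over_12h = FALSE,
                               config = default_config()) {
  m <- data.table::as.data.table(labeled)
  if (nrow(m) == 0) {
    return(data.table::data.table(
      child_id = character(), label = character(), pm25_mean = numeric(),
      pm25_median = numeric(), ratio_mean = numeric(),
      ratio_of_means = numeric(), minutes = integer(),
      time_proportion = numeric(), exposure_proportion = numeric()
    ))
  }
  guard <- config$metrics$ratio_pm10_min
  s <- m[, {
    pv <- pm_valid == TRUE
    rsel <- pv & is.finite(pm10_mean) & pm10_mean >= guard
    .(pm25_mean = mean_or_na(pm25_mean[pv]),
      pm25_median = if (any(pv)) median(pm25_mean[pv]) else NA_real_,
      ratio_mean = if (any(rsel)) mean(pm25_mean[rsel] / pm10_mean[rsel])
                   else NA_real_,
      ratio_of_means = if (any(rsel))
        mean(pm25_mean[rsel]) / mean(pm10_mean[rsel]) else NA_real_,
      minutes = .N,
      pm25_sum = sum(pm25_mean[pv], na.rm = TRUE))
  }, by = label]
  lab_ok <- s$label != "unknown"
  tot_min <- sum(s$minutes[lab_ok])
  tot_exp <- sum(s$pm25_sum[lab_ok])
  s[, time_proportion := NA_real_]
  s[, exposure_proportion := NA_real_]
  if (!gps_gap_over_12h) {
    if (tot_min > 0) s[lab_ok, time_proportion := minutes / tot_min]
    if (tot_exp > 0) s[lab_ok, exposure_proportion := pm25_sum / tot_exp]
  }
  s[, pm25_sum := NULL]
  s[, child_id := child_id]
  data.table::setcolorder(s, c("child_id", "label"))
  s[]
}

#' Diurnal exposure profiles by city
#'
#' Child-hour means (per child, calendar day and clock hour, over PM-valid
#' minutes) are pooled within each city, then summarised per clock hour with
#' median, mean, quartiles and the 5th/95th percentiles (linear
#' interpolation between order statistics). Hours with zero child-hours give
#' a record with missing statistics.
#'
#' @param labeled_by_child `data.table` of labelled minutes with `child_id`
#'   column (stack of per-child outputs).
#' @param city_map `data.table`/data.frame `child_id, city_id`.
#' @return `data.table` `city_id, hour, median, mean, q25, q75, p5, p95,
#'   n_child_hours`, 24 rows per city.
#' @export
diurnal_profiles <- function(labeled_by_child, city_map) {
  m <- data.table::as.data.table(labeled_by_child)
  cm <- data.table::as.data.table(city_map)[, .(child_id, city_id)]
  cities <- unique(cm$city_id)
  grid <- data.table::CJ(city_id = cities, hour = 0:23)
  if (nrow(m) == 0) {
    return(grid[, .(city_id, hour, median = NA_real_, mean = NA_real_,
                    q25 = NA_real_, q75 = NA_real_, p5 = NA_real_,
                    p95 = NA_real_, n_child_hours = 0L)])
  }
  v <- m[pm_valid == TRUE]
  v <- cm[v, on = "child_id"]
  ch <- v[, .(value = mean(pm25_mean)),
          by = .(city_id, child_id, date = as.Date(minute_start),
                 hour = as.integer(format(minute_start, "%H")))]
  prof <- ch[, .(
    median = median(value), mean = mean(value),
    q25 = quantile(value, 0.25, names = FALSE),
    q75 = quantile(value, 0.75, names = FALSE),
    p5 = quantile(value, 0.05, names = FALSE),
    p95 = quantile(value, 0.95, names = FALSE),
    n_child_hours = .N
  ), by = .(city_id, hour)]
  out <- prof[grid, on = c("city_id", "hour")]
  out[is.na(n_child_hours), n_child_hours := 0L]
  data.table::setorder(out, city_id, hour)
  out[]
}

#' WHO 24-h guideline compliance counts
#'
#' Counts days whose daily mean is strictly below the guideline values
#' (PM2.5: 15 ug/m3; PM10: 45 ug/m3 by default).
#'
#' @param daily Stacked [daily_means()] rows.
#' @param config Configuration list.
#' @return List `pm25_below`, `pm10_below`, `total_days`, `pm25_pct`,
#'   `pm10_pct` (percent of total days, `NA` when no days).
#' @export
guideline_compliance <- function(daily, config = default_config()) {
  m <- config$metrics
  d <- data.table::as.data.table(daily)
  total <- nrow(d)
  pm25_below <- if (total) sum(d$pm25_daily_mean < m$who_pm25, na.rm = TRUE) else 0L
  pm10_below <- if (total) sum(d$pm10_daily_mean < m$who_pm10, na.rm = TRUE) else 0L
  list(
    pm25_below = as.integer(pm25_below),
    pm10_below = as.integer(pm10_below),
    total_days = as.integer(total),
    pm25_pct = compliance_percent(pm25_below, total),
    pm10_pct = compliance_percent(pm10_below, total)
  )
}

#' Compliance percentage from counts
#' @param below Number of compliant days.
#' @param total Total days.
#' @return `below / total * 100`, `NA` when `total` is 0.
#' @export
compliance_percent <- function(below, total) {
  if (total <= 0) return(NA_real_)
  below / total * 100
}
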