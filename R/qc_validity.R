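#' Longest continuous run of PM-valid minutes
#'
#' "Continuous" tolerates short sensor hiccups: a run may contain internal
#' invalid stretches of at most `max_internal_gap_min` minutes, and only the
#' valid minutes are counted towards the run length. With
#' `count_clock_time = TRUE` the run length is instead measured in elapsed
#' clock minutes from the run's first to last valid minute.
#'
#' @param minutes Minute records (time-ordered), see [aggregate_minutes()].
#' @param max_internal_gap_min Largest tolerated internal invalid stretch.
#' @param count_clock_time Count elapsed clock minutes instead of valid
#'   minutes.
#' @return Length of the longest run, in minutes (0 for empty input).
#' @export
longest_valid_run <- function(minutes, max_internal_gap_min = 5,
                              count_clock_time = FALSE) {
  if (is.null(minutes) || nrow(minutes) == 0) return(0L)
  v <- minutes$pm_valid
  if (!any(v)) return(0L)
  r <- rle(v)
  # merge invalid stretches <= gap into neighbouring valid runs
  keep_block <- r$values | r$lengths <= max_internal_gap_min
  # block ids: consecutive kept blocks bounded by long invalid stretches
  run_id <- cumsum(!keep_block)
  best <- 0L
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  for (g in unique(run_id[keep_block])) {
    sel <- keep_block & run_id == g
    if (!any(r$values[sel])) next
    vsel <- which(sel & r$values)
    if (count_clock_time) {
      span <- idx_end[max(vsel)] - idx_start[min(vsel)] + 1L
      best <- max(best, span)
    } else {
      best <- max(best, sum(r$lengths[vsel]))
    }
  }
  as.integer(best)
}

#' Per-child validity report
#'
#' Applies the inclusion rule (more than 24 h of continuous valid data,
#' strict inequality) and the GPS-gap rule (more than 12 h of missing GPS
#' flags the child out of proportion-of-exposure analyses only).
#'
#' @param minutes Minute records for one child (time-ordered).
#' @param child_id Child identifier carried into the report.
#' @param config Configuration list.
#' @return One-row `data.table`: `child_id, total_minutes, valid_pm_minutes,
#'   longest_continuous_valid_minutes, passes_24h, gps_missing_hours,
#'   gps_gap_over_12h`.
#' @export
validity_report <- function(minutes, child_id = NA_character_,
                            config = default_config()) {
  q <- config$qc
  n <- if (is.null(minutes)) 0L else nrow(minutes)
  valid <- if (n) sum(minutes$pm_valid) else 0L
  run <- longest_valid_run(minutes, q$max_internal_gap_min,
                           q$count_clock_time)
  gps_missing <- if (n) sum(!minutes$gps_valid) / 60 else 0
  data.table::data.table(
    child_id = child_id,
    total_minutes = as.integer(n),
    valid_pm_minutes = as.integer(valid),
    longest_continuous_valid_minutes = as.integer(run),
    passes_24h = run > q$min_continuous_minutes,
    gps_missing_hours = gps_missing,
    gps_gap_over_12h = gps_missing > q$gps_gap_hours
  )
}

#' Exclusion reason levels
#' @return Character vector of the recognised exclusion reasons.
#' @export
exclusion_reasons <- function() {
  c("no_questionnaire", "withdrew", "backpack_not_taken_to_school",
    "monitor_failure", "insufficient_continuous_data", "none")
}

#' Build the cohort exclusion ledger
#'
#' Assigns exactly one `{included, excluded}` status per monitored child, with
#' a reason from [exclusion_reasons()]. Precedence follows the screening
#' order: withdrawal, missing questionnaire, monitor failure, backpack never
#' taken to school (zero school-tagged minutes on every school day), then the
#' continuous-data rule.
#'
#' @param cohort Cohort table (one row per monitored child). Children whose
#'   questionnaire was never filled in are still listed here but flagged in
#'   `questionnaires`.
#' @param questionnaires Character vector of child ids with a completed
#'   questionnaire.
#' @param validity_reports `data.table` of stacked [validity_report()] rows.
#' @param tag_summaries Optional `data.table` `child_id, school_minutes`
#'   giving school-tagged minute counts (0 triggers the backpack rule);
#'   children absent from it are not assessed against that rule.
#' @param withdrew Character vector of child ids who withdrew.
#' @param monitor_failures Character vector of child ids with failed units.
#' @return `data.table` `child_id, status, reason`, one row per cohort child.
#' @export
build_exclusion_ledger <- function(cohort, questionnaires, validity_reports,
                                   tag_summaries = NULL,
                                   withdrew = character(),
                                   monitor_failures = character()) {
  ids <- as.character(cohort$child_id)
  extra <- setdiff(validity_reports$child_id, ids)
  if (length(extra)) {
    stop("consistency error: trace child(ren) missing from cohort: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  vr <- data.table::as.data.table(validity_reports)
  reason <- rep("none", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    if (id %in% withdrew) {
      reason[i] <- "withdrew"
    } else if (!(id %in% questionnaires)) {
      reason[i] <- "no_questionnaire"
    } else if (id %in% monitor_failures) {
      reason[i] <- "monitor_failure"
    } else if (!is.null(tag_summaries) && id %in% tag_summaries$child_id &&
               tag_summaries$school_minutes[match(id, tag_summaries$child_id)] == 0) {
      reason[i] <- "backpack_not_taken_to_school"
    } else if (id %in% vr$child_id &&
               !vr$passes_24h[match(id, vr$child_id)]) {
      reason[i] <- "insufficient_continuous_data"
    }
  }
  data.table::data.table(
    child_id = ids,
    status = ifelse(reason == "none", "included", "excluded"),
    reason = reason
  )
}
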