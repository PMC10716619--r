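full_day <- function(day, pm25, pm10 = 2 * pm25) {
  make_minutes(1440, start = t0(0, day = day), pm25 = pm25, pm10 = pm10)
}

test_that("daily_means averages valid minutes per calendar day", {
  d <- daily_means(full_day("2021-09-07", 10), "a")  # a Tuesday
  expect_equal(d$pm25_daily_mean, 10)
  expect_equal(d$valid_minutes, 1440L)
  expect_equal(d$day_of_week, "Tuesday")

  half <- full_day("2021-09-07", c(rep(10, 720), rep(30, 720)))
  expect_equal(daily_means(half, "a")$pm25_daily_mean, 20)

  # 900 valid minutes < 1080 -> day omitted
  low <- full_day("2021-09-07", 10)
  low$pm_valid[1:540] <- FALSE
  expect_message(d3 <- daily_means(low, "a"), "below coverage")
  expect_equal(nrow(d3), 0)
  expect_equal(attr(d3, "n_days_dropped"), 1)

  # Friday is outside the modelling day-of-week levels
  fri <- full_day("2021-09-10", 10)
  expect_message(d4 <- daily_means(fri, "a"), "below coverage")
  expect_equal(nrow(d4), 0)
})

test_that("microenv_summaries computes proportions and ratios", {
  m <- full_day("2021-09-07", 10)
  m$label <- "home"; m$label_source <- "geofence"
  s <- microenv_summaries(m, "a")
  expect_equal(s$time_proportion[s$label == "home"], 1)
  expect_equal(s$exposure_proportion[s$label == "home"], 1)

  # equal minutes at 10 (home) and 30 (school): time .5/.5, exposure .25/.75
  m2 <- full_day("2021-09-07", c(rep(10, 720), rep(30, 720)))
  m2$label <- rep(c("home", "school"), each = 720)
  m2$label_source <- "geofence"
  s2 <- microenv_summaries(m2, "a")
  expect_equal(s2$time_proportion, c(0.5, 0.5))
  expect_equal(s2$exposure_proportion[s2$label == "home"], 0.25)
  expect_equal(s2$exposure_proportion[s2$label == "school"], 0.75)

  # pm25=5, pm10=10 every minute -> ratio_mean 0.5
  m3 <- full_day("2021-09-07", 5, pm10 = 10)
  m3$label <- "home"; m3$label_source <- "geofence"
  expect_equal(microenv_summaries(m3, "a")$ratio_mean, 0.5)

  # GPS-gap children keep means but lose proportions
  s4 <- microenv_summaries(m2, "a", gps_gap_over_12h = TRUE)
  expect_true(all(is.na(s4$time_proportion)))
  expect_false(any(is.na(s4$pm25_mean)))
})

test_that("proportions sum to 1 and exposure is conserved across labels", {
  set.seed(23)
  for (rep in 1:5) {
    n <- 1440
    m <- make_minutes(n, start = t0(0, day = "2021-09-07"),
                      pm25 = rlnorm(n, 3, 0.5))
    m$label <- sample(c("home", "school", "commute", "other", "unknown"),
                      n, replace = TRUE, prob = c(.5, .25, .1, .1, .05))
    m$label_source <- ifelse(m$label == "unknown", "none", "geofence")
    s <- microenv_summaries(m, "x")
    ok <- s$label != "unknown" & s$minutes > 0
    expect_equal(sum(s$time_proportion[ok]), 1, tolerance = 1e-9)
    expect_equal(sum(s$exposure_proportion[ok]), 1, tolerance = 1e-9)
    # conservation: sum(minutes x label mean) = total x overall mean
    pv <- m$pm_valid
    expect_equal(sum(s$pm25_mean * tapply(pv, m$label, sum)[s$label]),
                 sum(m$pm25_mean[pv]), tolerance = 1e-9)
  }
})

test_that("diurnal profiles are flat for constant traces and ordered", {
  m <- full_day("2021-09-07", 12)
  m$child_id <- "a"
  prof <- diurnal_profiles(m, data.frame(child_id = "a", city_id = "X"))
  expect_equal(nrow(prof), 24)
  expect_true(all(prof$median == 12))
  expect_true(all(prof$mean == 12))
  # quantile ordering invariant
  set.seed(29)
  m2 <- full_day("2021-09-07", rlnorm(1440, 3, 0.6))
  m2$child_id <- "a"
  p2 <- diurnal_profiles(m2, data.frame(child_id = "a", city_id = "X"))
  ok <- p2$n_child_hours > 0
  expect_true(all(p2$p5[ok] <= p2$q25[ok] & p2$q25[ok] <= p2$median[ok] &
                  p2$median[ok] <= p2$q75[ok] & p2$q75[ok] <= p2$p95[ok]))
  # empty city -> rows with missing stats
  p3 <- diurnal_profiles(m2[0], data.frame(child_id = "a", city_id = "X"))
  expect_equal(nrow(p3), 24)
  expect_true(all(is.na(p3$median)))
  expect_true(all(p3$n_child_hours == 0))
})

test_that("planted evening cooking spike dominates the diurnal profile", {
  g <- small_gen_config(n_cities = 1, n_children = 2, resolution_s = 10)
  # force biomass cookers so the cooking multiplier applies
  g$prevalences$cooker_type <- c(
    "Electric" = 0, "Gas" = 0, "Gas and biomass" = 0,
    "Coal or wood (biomass)" = 1, "Kerosene" = 0,
    "Open fire and biomass" = 0, "Not reported" = 0)
  cg <- generate_cohort(g, seed = 11)
  tr <- generate_traces(cg$cohort, cg$truth, g, seed = 11)
  cfg <- config_for_resolution(10)
  lab <- data.table::rbindlist(lapply(names(tr$traces), function(id) {
    m <- aggregate_minutes(tr$traces[[id]], cfg)
    m$child_id <- id
    m
  }))
  lab$label <- "home"; lab$label_source <- "geofence"
  prof <- diurnal_profiles(lab, cg$cohort[, c("child_id", "city_id")])
  peak_hours <- prof$hour[order(-prof$mean)][1:2]
  expect_setequal(peak_hours, c(5, 18))
})

test_that("guideline compliance counts use strict inequalities", {
  d <- data.table::data.table(
    pm25_daily_mean = c(10.0, 14.9, 15.0, 20.0, 44.9),
    pm10_daily_mean = c(30, 44.9, 45.0, 50, 10))
  gc <- guideline_compliance(d)
  expect_equal(gc$pm25_below, 2L)
  expect_equal(gc$pm10_below, 3L)
  expect_equal(gc$total_days, 5L)
  expect_equal(gc$pm25_pct, 40)
  z <- guideline_compliance(d[0])
  expect_equal(z$pm25_below, 0L)
  expect_equal(z$total_days, 0L)
  expect_true(is.na(z$pm25_pct))
})
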