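test_that("read_trace handles well-formed, malformed and disordered files", {
  ts <- format(t0(10) + 0:2, "%Y-%m-%dT%H:%M:%S")
  p <- write_toy_trace(paste(ts, c(10, 11, 12), c(20, 21, 22),
                             -15.7861, 35.0058, sep = ","))
  s <- read_trace(p)
  expect_equal(nrow(s), 3)
  expect_equal(attr(s, "malformed"), 0L)
  expect_equal(s$pm25, c(10, 11, 12))

  p2 <- write_toy_trace(paste(ts, c(10, "oops", 12), 20, -15.78, 35.0,
                              sep = ","))
  expect_message(s2 <- read_trace(p2), "1 malformed")
  expect_equal(attr(s2, "malformed"), 1L)
  expect_true(is.na(s2$pm25[2]))
  expect_equal(s2$pm10, rep(20, 3))

  p3 <- write_toy_trace(paste(ts[c(1, 3, 2)], 10, 20, -15.78, 35.0,
                              sep = ","))
  expect_error(read_trace(p3), "row 3")

  p4 <- tempfile(fileext = ".csv")
  writeLines(c("timestamp,pm25,lat,lon", paste(ts[1], 10, -15.78, 35.0,
                                               sep = ",")), p4)
  expect_error(read_trace(p4), "schema error.*pm10")
})

test_that("read_trace blanks values beyond the physical cap", {
  ts <- format(t0(10) + 0:1, "%Y-%m-%dT%H:%M:%S")
  p <- write_toy_trace(paste(ts, c(10, 25000), 20, -15.78, 35.0, sep = ","))
  s <- read_trace(p)
  expect_true(is.na(s$pm25[2]))
  expect_equal(s$pm25[1], 10)
})

test_that("aggregate_minutes follows the 30-valid-sample rule and spans gaps", {
  base <- t0(10)
  full <- data.table::data.table(
    timestamp = base + 0:59, pm25 = 10, pm10 = 20,
    lat = -15.78, lon = 35.0)
  m <- aggregate_minutes(full)
  expect_equal(nrow(m), 1)
  expect_equal(m$pm25_mean, 10)
  expect_true(m$pm_valid)

  # 20 valid samples: mean still reported, minute invalid
  part <- full[1:20]
  m2 <- aggregate_minutes(part)
  expect_false(m2$pm_valid)
  expect_equal(m2$pm25_mean, 10)
  expect_equal(m2$n_samples_valid, 20L)

  # arithmetic mean of 1..60
  ramp <- data.table::data.table(
    timestamp = base + 0:59, pm25 = 1:60, pm10 = 2 * (1:60),
    lat = NA_real_, lon = NA_real_)
  expect_equal(aggregate_minutes(ramp)$pm25_mean, 30.5)

  # empty input -> empty output
  expect_equal(nrow(aggregate_minutes(full[0])), 0)

  # span property: output rows = distinct calendar minutes spanned,
  # independent of sampling gaps
  set.seed(5)
  for (rep in 1:5) {
    idx <- sort(sample(0:(30 * 60 - 1), 200))
    sp <- data.table::data.table(timestamp = base + idx, pm25 = 5,
                                 pm10 = 10, lat = NA_real_, lon = NA_real_)
    m3 <- aggregate_minutes(sp)
    span <- as.numeric(difftime(max(m3$minute_start), min(m3$minute_start),
                                units = "mins")) + 1
    expect_equal(nrow(m3), span)
  }
})

test_that("trace round-trip preserves values to 6 decimals", {
  set.seed(11)
  s <- data.table::data.table(
    timestamp = t0(10) + 0:99,
    pm25 = runif(100, 0, 300), pm10 = runif(100, 0, 400),
    lat = -15.78 + rnorm(100, 0, 0.001), lon = 35.0 + rnorm(100, 0, 0.001))
  p <- tempfile(fileext = ".csv")
  write_trace(s, p)
  r <- read_trace(p)
  expect_equal(r$pm25, s$pm25, tolerance = 1e-6)
  expect_equal(r$lat, s$lat, tolerance = 1e-6)
  expect_equal(r$timestamp, s$timestamp)
})

test_that("write_outputs is deterministic and refuses collisions", {
  tab <- data.table::data.table(a = 1:3, b = c("x", "y", "z"))
  d1 <- file.path(tempfile(), "out")
  write_outputs(list(t1 = tab), d1)
  h1 <- tools::md5sum(file.path(d1, "t1.csv"))
  expect_error(write_outputs(list(t1 = tab), d1), "collision")
  write_outputs(list(t1 = tab), d1, force = TRUE)
  expect_identical(unname(tools::md5sum(file.path(d1, "t1.csv"))),
                   unname(h1))
  # empty table -> header-only CSV
  d2 <- tempfile()
  write_outputs(list(empty = tab[0]), d2)
  expect_equal(readLines(file.path(d2, "empty.csv")), "a,b")
})

test_that("cohort/meteorology/diary readers validate their schemas", {
  g <- small_gen_config()
  cg <- generate_cohort(g, seed = 4)
  p <- tempfile(fileext = ".csv")
  write_outputs(list(cohort = cg$cohort), dirname(p), force = TRUE)
  co <- read_cohort(file.path(dirname(p), "cohort.csv"))
  expect_s3_class(co$cooker_type, "factor")
  expect_setequal(levels(co$gender), c("Female", "Male"))

  bad <- data.table::copy(cg$cohort)
  bad$gender <- "Nonbinary"  # not an enumerated questionnaire level
  pb <- tempfile(fileext = ".csv")
  data.table::fwrite(bad, pb)
  expect_error(read_cohort(pb), "invalid gender")

  pm <- tempfile(fileext = ".csv")
  writeLines(c("city_id,date,temp_c,rh_pct,wind_ms",
               "Blantyre,2021-09-06,28,120,3"), pm)
  expect_error(read_meteorology(pm), "rh_pct")

  pd <- tempfile(fileext = ".csv")
  writeLines(c("child_id,date,commute_mode_to_school",
               "c1,2021-09-06,Walk", "c1,2021-09-06,Walk"), pd)
  expect_error(read_diary(pd), "duplicate")
})

test_that("config round-trips through JSON and rejects unknown keys", {
  cfg <- default_config()
  p <- tempfile(fileext = ".json")
  write_config(cfg, p)
  cfg2 <- read_config(p)
  expect_equal(cfg2$qc$minute_valid_min, cfg$qc$minute_valid_min)
  expect_equal(cfg2$metrics$who_pm25, 15)
  bad <- jsonlite::read_json(p, simplifyVector = TRUE)
  bad$qc$minuet_valid_min <- 10
  pb <- tempfile(fileext = ".json")
  jsonlite::write_json(bad, pb, auto_unbox = TRUE)
  expect_error(read_config(pb), "unknown config key")
})
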