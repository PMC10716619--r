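# Synthetic cohort generator. The stated world: six cities with published
# geometric means/GSDs of children's daily PM2.5 exposure, Monday ~10:00 to
# Friday ~10:00 monitoring at 1-s cadence, home/school/commute schedules,
# lognormal child- and day-level heterogeneity, multiplicative determinant
# effects, microenvironment-specific PM2.5:PM10 ratios, GPS jitter and
# dropout. Every draw is reproducible from one seed and the ground truth is
# returned alongside the data.

#' Default synthetic-generator configuration
#'
#' City rows carry the published per-city daily-exposure geometric means and
#' geometric SDs, child counts, meteorology means/SDs, and the
#' microenvironment-specific PM2.5:PM10 ratios (school lower than home in
#' the four dusty-school cities, reflecting resuspended coarse dust on
#' unpaved grounds). Planted determinant effects default to the published
#' point estimates converted to multiplicative factors; they are calibration
#' conveniences for recovery testing, not claims of truth.
#'
#' @return Nested named list; see the methods vignette for the rationale of
#'   every default.
#' @export
default_generator_config <- function() {
  list(
    cities = data.frame(
      city_id = c("Blantyre", "Durban", "Harare", "Kumasi", "Lagos", "Moshi"),
      lat = c(-15.786, -29.858, -17.829, 6.688, 6.524, -3.349),
      lon = c(35.006, 31.022, 31.053, -1.624, 3.379, 37.340),
      gm = c(45.7, 18.8, 21.4, 18.3, 24.1, 29.1),
      gsd = c(1.6, 2.2, 1.6, 1.6, 1.5, 1.5),
      home_ratio = c(0.70, 0.72, 0.72, 0.70, 0.70, 0.70),
      school_ratio = c(0.45, 0.70, 0.70, 0.45, 0.45, 0.45),
      commute_ratio = c(0.60, 0.71, 0.71, 0.75, 0.65, 0.65),
      temp_mean = c(28.2, 19.1, 22.5, 27.4, 27.0, 22.5),
      temp_sd = c(4.2, 1.9, 4.8, 2.0, 1.2, 2.2),
      rh_mean = c(44.4, 72.1, 54.8, 77.1, 82.2, 58.9),
      rh_sd = c(14.2, 8.9, 18.1, 8.9, 5.7, 8.9),
      wind_mean = c(3.8, 2.8, 4.0, 1.8, 3.1, 3.7),
      wind_sd = c(1.3, 0.8, 1.2, 0.6, 0.8, 1.5),
      n_children = c(24L, 47L, 43L, 61L, 61L, 61L),
      n_schools = c(4L, 7L, 7L, 9L, 8L, 8L),
      stringsAsFactors = FALSE
    ),
    sigma_location = 0,       # city effects are realised through stated GMs
    child_var_share = 0.6,    # share of log(gsd)^2 assigned to children
    sigma_child = NA_real_,   # override; NA -> sqrt(share) * log(gsd_city)
    sigma_day = NA_real_,     # override; NA -> sqrt(1 - share) * log(gsd)
    effects = list(
      smoking_at_home = c("Presence of smokers" = 1.230),
      cooker_type = c("Coal or wood (biomass)" = 1.271),
      lighting_use = c("Kerosene lamp and other" = 1.302),
      school_ground_surface = c("Paved" = 0.628),
      commute_mode = c("No commute" = 0.817)
    ),
    met_effects = c(temp_c = 1.056, wind_ms = 0.916),  # per unit deviation
    prevalences = list(
      near_waste_burning = c("No" = 0.81, "Yes" = 0.19),
      near_construction = c("No" = 0.92, "Yes" = 0.08),
      help_with_cooking = c("No" = 0.74, "Yes" = 0.26),
      contact_with_animals = c("No" = 0.85, "Yes" = 0.15),
      commute_mode = c("Walk" = 0.46, "Motorised" = 0.32, "Mixed mode" = 0.09,
                       "No commute" = 0.09, "Unclassified" = 0.04),
      cooker_location = c("Inside" = 0.72, "Outside" = 0.26,
                          "Not reported" = 0.02),
      cooker_type = c("Electric" = 0.39, "Gas" = 0.26, "Gas and biomass" = 0.22,
                      "Coal or wood (biomass)" = 0.06, "Kerosene" = 0.02,
                      "Open fire and biomass" = 0.04, "Not reported" = 0.01),
      lighting_use = c("Electric only" = 0.33, "Candle" = 0.18,
                       "Candle and other" = 0.17,
                       "Kerosene lamp and other" = 0.08,
                       "Rechargeable/solar lamp or torch" = 0.22,
                       "Not reported" = 0.02),
      smoking_at_home = c("No smokers" = 0.79, "Presence of smokers" = 0.19,
                          "Not reported" = 0.02),
      gender = c("Female" = 0.60, "Male" = 0.40),
      near_busy_road = c("Yes" = 0.73, "No" = 0.25, "Not reported" = 0.02),
      school_ground_surface = c("Loose dirt" = 0.58, "Packed dirt" = 0.06,
                                "Broken paving" = 0.07, "Paved" = 0.29)
    ),
    schedule = list(school = c(8, 14), commute_am = c(7, 8),
                    commute_pm = c(14, 15)),
    microenv_factors = c(home = 0.95, school = 1.35, commute = 1.15),
    cooking_multiplier = 3.0,
    cooking_hours = c(5, 18),   # 05:00-06:00 and 18:00-19:00 peaks
    gps_jitter_m = 30,
    dropout_rate = 0.10,
    dropout_mean_min = 10,
    ar_rho = 0.9,
    ar_sd = 0.35,
    resolution_s = 1,
    start_monday = "2021-09-06",
    n_days = 4,
    home_dist_m = c(600, 2500),
    n_gps_gap_children = 0
  )
}

validate_generator_config <- function(g) {
  stopifnot(all(g$cities$gm > 0), all(g$cities$gsd > 1),
            all(unlist(g$effects) > 0), all(g$met_effects > 0),
            g$dropout_rate >= 0, g$dropout_rate <= 1,
            g$ar_rho >= 0, g$ar_rho < 1, g$gps_jitter_m >= 0)
  for (d in names(g$prevalences)) {
    p <- g$prevalences[[d]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-6) {
      stop("config error: prevalence vector for ", d,
           " must be non-negative and sum to 1", call. = FALSE)
    }
  }
  invisible(g)
}

sigma_child_city <- function(g, gsd) {
  if (is.finite(g$sigma_child)) rep(g$sigma_child, length(gsd))
  else sqrt(g$child_var_share) * log(gsd)
}

sigma_day_city <- function(g, gsd) {
  if (is.finite(g$sigma_day)) rep(g$sigma_day, length(gsd))
  else sqrt(1 - g$child_var_share) * log(gsd)
}

offset_latlon <- function(lat, lon, dx_m, dy_m) {
  list(lat = lat + dy_m / 111320,
       lon = lon + dx_m / (111320 * cos(lat * pi / 180)))
}

#' Generate a synthetic cohort with ground truth
#'
#' Children are assigned to cities and schools, questionnaire determinants
#' drawn from the configured prevalences (school-ground surface drawn per
#' school), home/school anchor coordinates placed on the map, and per-child
#' random intercepts drawn on the log scale.
#'
#' @param config Generator configuration, see [default_generator_config()].
#' @param seed Integer seed; the cohort is a pure function of it.
#' @return List `cohort` (child table, see [read_cohort()] schema) and
#'   `truth` (anchors, random intercepts, planted log effects, seed).
#' @export
generate_cohort <- function(config = default_generator_config(), seed = 1) {
  validate_generator_config(config)
  set.seed(seed)
  ct <- config$cities
  dl <- determinant_levels()
  rows <- list(); anchors <- list()
  b_child <- numeric(0)
  start <- as.POSIXct(paste0(config$start_monday, "T10:00:00"),
                      format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  for (ci in seq_len(nrow(ct))) {
    n <- ct$n_children[ci]
    if (n == 0) next
    city <- ct$city_id[ci]
    nsch <- max(1L, ct$n_schools[ci])
    sch_ids <- sprintf("%s_S%02d", city, seq_len(nsch))
    sch_xy <- offset_latlon(ct$lat[ci], ct$lon[ci],
                            runif(nsch, -3000, 3000), runif(nsch, -3000, 3000))
    sch_surface <- sample(names(config$prevalences$school_ground_surface),
                          nsch, replace = TRUE,
                          prob = config$prevalences$school_ground_surface)
    sch_of_child <- sample(seq_len(nsch), n, replace = TRUE)
    ids <- sprintf("%s_C%03d", city, seq_len(n))
    det <- data.frame(child_id = ids, city_id = city,
                      school_id = sch_ids[sch_of_child],
                      monitoring_start = start,
                      stringsAsFactors = FALSE)
    for (d in names(dl)) {
      if (d == "school_ground_surface") {
        det[[d]] <- factor(sch_surface[sch_of_child], levels = dl[[d]])
      } else {
        p <- config$prevalences[[d]]
        det[[d]] <- factor(sample(names(p), n, replace = TRUE, prob = p),
                           levels = dl[[d]])
      }
    }
    rows[[city]] <- det
    # anchors: home placed around the child's school
    dist <- runif(n, config$home_dist_m[1], config$home_dist_m[2])
    bear <- runif(n, 0, 2 * pi)
    home <- offset_latlon(sch_xy$lat[sch_of_child], sch_xy$lon[sch_of_child],
                          dist * cos(bear), dist * sin(bear))
    anchors[[city]] <- data.frame(
      child_id = ids,
      home_lat = home$lat, home_lon = home$lon,
      school_lat = sch_xy$lat[sch_of_child],
      school_lon = sch_xy$lon[sch_of_child],
      stringsAsFactors = FALSE
    )
    sc <- sigma_child_city(config, ct$gsd[ci])
    b <- rnorm(n, 0, sc)
    names(b) <- ids
    b_child <- c(b_child, b)
  }
  cohort <- data.table::rbindlist(rows)
  anchors <- data.table::rbindlist(anchors)
  gap_children <- character()
  if (config$n_gps_gap_children > 0 && nrow(cohort) > 0) {
    gap_children <- sample(cohort$child_id,
                           min(config$n_gps_gap_children, nrow(cohort)))
  }
  truth <- list(
    anchors = anchors,
    b_child = b_child,
    effects_log = planted_effects_log(config),
    gps_gap_children = gap_children,
    seed = seed,
    config = config
  )
  list(cohort = cohort[], truth = truth)
}

# planted effects named like the fitted model's design columns
planted_effects_log <- function(config) {
  out <- c()
  for (d in names(config$effects)) {
    f <- config$effects[[d]]
    v <- log(f)
    names(v) <- paste0(d, names(f))
    out <- c(out, v)
  }
  c(out, log(config$met_effects))
}

#' Generate daily meteorology per city
#' @param config Generator configuration.
#' @param dates Vector of `Date`s.
#' @param seed Integer seed.
#' @return `data.table` `city_id, date, temp_c, rh_pct, wind_ms`.
#' @export
generate_meteorology <- function(config = default_generator_config(),
                                 dates, seed = 1) {
  set.seed(seed + 1L)
  ct <- config$cities
  grid <- data.table::CJ(city_id = ct$city_id, date = as.Date(dates))
  i <- match(grid$city_id, ct$city_id)
  grid[, temp_c := rnorm(.N, ct$temp_mean[i], ct$temp_sd[i])]
  grid[, rh_pct := pmin(99, pmax(1, rnorm(.N, ct$rh_mean[i], ct$rh_sd[i])))]
  grid[, wind_ms := pmax(0.1, rnorm(.N, ct$wind_mean[i], ct$wind_sd[i]))]
  grid[]
}

# per child-day mean of log exposure, before day-level noise
child_day_logmu <- function(cohort, truth, met, config) {
  ct <- config$cities
  dt <- data.table::as.data.table(cohort)
  eff <- truth$effects_log
  base <- log(ct$gm[match(dt$city_id, ct$city_id)]) +
    truth$b_child[match(dt$child_id, names(truth$b_child))]
  for (d in names(config$effects)) {
    for (lv in names(config$effects[[d]])) {
      hit <- as.character(dt[[d]]) == lv
      base <- base + ifelse(hit, eff[paste0(d, lv)], 0)
    }
  }
  out <- data.table::data.table(child_id = dt$child_id, city_id = dt$city_id,
                                base = base)
  m <- data.table::as.data.table(met)
  out <- out[m, on = "city_id", allow.cartesian = TRUE]
  i <- match(out$city_id, ct$city_id)
  out[, log_mu := base + eff["temp_c"] * (temp_c - ct$temp_mean[i]) +
        eff["wind_ms"] * (wind_ms - ct$wind_mean[i])]
  out[, .(child_id, city_id, date, log_mu)]
}

#' Generate daily exposures directly from the lognormal model
#'
#' Fast path for model-calibration studies: draws the per child-day daily
#' mean PM2.5 from the generating model (city GM x child intercept x planted
#' determinant factors x meteorology factors x day-level lognormal noise)
#' without simulating minute traces. PM10 is derived from the time-weighted
#' microenvironment ratio profile.
#'
#' @param cohort,truth From [generate_cohort()].
#' @param config Generator configuration.
#' @param seed Integer seed.
#' @param met Optional meteorology table; generated from `seed` when `NULL`.
#' @return `data.table` in the [daily_means()] schema plus `city_id`,
#'   with attribute `met` (the meteorology used).
#' @export
generate_daily_exposures <- function(cohort, truth,
                                     config = default_generator_config(),
                                     seed = 1, met = NULL) {
  start <- as.Date(config$start_monday)
  dates <- start + seq_len(config$n_days) - 1
  if (is.null(met)) met <- generate_meteorology(config, dates, seed)
  set.seed(seed + 2L)
  mu <- child_day_logmu(cohort, truth, met, config)
  ct <- config$cities
  i <- match(mu$city_id, ct$city_id)
  sd_day <- sigma_day_city(config, ct$gsd)[i]
  mu[, pm25_daily_mean := exp(log_mu + rnorm(.N, 0, sd_day))]
  # time-weighted PM10: minute pm10 = pm25 / ratio(label)
  w <- c(home = 16 / 24, school = 6 / 24, commute = 2 / 24)
  f <- config$microenv_factors / sum(config$microenv_factors * w)
  conv <- (w["home"] * f["home"] / ct$home_ratio[i] +
           w["school"] * f["school"] / ct$school_ratio[i] +
           w["commute"] * f["commute"] / ct$commute_ratio[i])
  mu[, pm10_daily_mean := pm25_daily_mean * conv]
  out <- mu[, .(child_id, city_id, date, pm25_daily_mean, pm10_daily_mean,
                valid_minutes = 1440L, day_of_week = weekdays(date))]
  data.table::setattr(out, "met", met)
  data.table::setattr(out, "seed", seed)
  out[]
}

# schedule -> true label for a vector of minute timestamps
schedule_labels <- function(minute_start, config) {
  h <- as.integer(format(minute_start, "%H"))
  wd <- weekdays(as.Date(minute_start))
  s <- config$schedule
  lab <- rep("home", length(h))
  school_day <- wd %in% c("Monday", "Tuesday", "Wednesday", "Thursday",
                          "Friday")
  lab[school_day & h >= s$commute_am[1] & h < s$commute_am[2]] <- "commute"
  lab[school_day & h >= s$commute_pm[1] & h < s$commute_pm[2]] <- "commute"
  lab[school_day & h >= s$school[1] & h < s$school[2]] <- "school"
  lab
}

#' Generate second-level sensor traces with known minute labels
#'
#' For each child, 96 h of samples from the configured Monday 10:00 start:
#' minute-level true exposure (city GM x child intercept x normalised
#' microenvironment factor x planted effects x meteorology x AR(1) lognormal
#' minute noise, with early-morning and evening cooking multipliers in
#' biomass/open-fire homes), PM10 from the label-specific PM2.5:PM10 ratio,
#' and GPS as anchor (or commute path) plus Gaussian jitter with dropout
#' segments. Commute paths run fence edge to fence edge so that in the
#' noiseless limit the geofence tagger reproduces the schedule exactly.
#'
#' @param cohort,truth From [generate_cohort()].
#' @param config Generator configuration.
#' @param seed Integer seed.
#' @param children Optional subset of child ids (default: all).
#' @param resolution_s Sampling period in seconds (must divide 60).
#' @return List: `traces` (named list of sensor-sample `data.table`s),
#'   `labels` (`data.table` `child_id, minute_start, true_label`),
#'   `met` (meteorology used), `seed`.
#' @export
generate_traces <- function(cohort, truth,
                            config = default_generator_config(), seed = 1,
                            children = NULL,
                            resolution_s = config$resolution_s) {
  stopifnot(60 %% resolution_s == 0, nrow(cohort) > 0)
  ids <- if (is.null(children)) cohort$child_id else children
  start <- as.POSIXct(paste0(config$start_monday, "T10:00:00"),
                      format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  n_min <- 96L * 60L
  minute_start <- start + 60 * (seq_len(n_min) - 1)
  dates <- sort(unique(as.Date(minute_start)))
  met <- generate_meteorology(config, dates, seed)
  mu <- child_day_logmu(cohort[cohort$child_id %in% ids, ], truth, met, config)
  ct <- config$cities
  lab <- schedule_labels(minute_start, config)
  hod <- as.integer(format(minute_start, "%H"))
  date_of <- as.Date(minute_start)
  cook_min <- hod %in% config$cooking_hours
  step <- resolution_s
  per_min <- 60L %/% step
  offs <- step * (seq_len(per_min) - 1)

  traces <- list()
  labels <- list()
  for (id in ids) {
    set.seed(seed + 10L + match(id, cohort$child_id))
    row <- cohort[cohort$child_id == id, ]
    ci <- match(row$city_id, ct$city_id)
    anc <- truth$anchors[truth$anchors$child_id == id, ]
    # daily base incl. day-level noise
    mu_c <- mu[child_id == id]
    sd_day <- sigma_day_city(config, ct$gsd)[ci]
    day_noise <- setNames(rnorm(length(dates), 0, sd_day), as.character(dates))
    log_base <- mu_c$log_mu[match(date_of, mu_c$date)] +
      day_noise[as.character(date_of)]
    # microenvironment + cooking factor profile, normalised per day
    f <- config$microenv_factors[lab]
    biomass <- as.character(row$cooker_type) %in%
      c("Coal or wood (biomass)", "Open fire and biomass")
    if (biomass) f <- f * ifelse(cook_min & lab == "home",
                                 config$cooking_multiplier, 1)
    f <- f / stats::ave(f, date_of, FUN = mean)
    # AR(1) lognormal minute noise, unit mean
    a <- as.numeric(stats::arima.sim(
      list(ar = config$ar_rho), n = n_min,
      sd = config$ar_sd * sqrt(1 - config$ar_rho^2)))
    noise <- exp(a - config$ar_sd^2 / 2)
    pm25 <- exp(log_base) * f * noise
    ratios <- c(home = ct$home_ratio[ci], school = ct$school_ratio[ci],
                commute = ct$commute_ratio[ci])
    pm10 <- pm25 / ratios[lab]
    pos <- commute_positions(minute_start, lab, anc, config)
    gps_na <- dropout_minutes(n_min, config)
    if (id %in% truth$gps_gap_children) {
      gap_start <- as.POSIXct(paste0(dates[2], "T18:00:00"),
                              format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
      gps_na <- gps_na | (minute_start >= gap_start &
                            minute_start < gap_start + 14 * 3600)
    }
    # expand to seconds
    idx <- rep(seq_len(n_min), each = per_min)
    ts <- rep(minute_start, each = per_min) + rep(offs, n_min)
    n_s <- length(ts)
    jit <- config$gps_jitter_m
    lat_s <- pos$lat[idx] + rnorm(n_s, 0, jit) / 111320
    lon_s <- pos$lon[idx] + rnorm(n_s, 0, jit) /
      (111320 * cos(ct$lat[ci] * pi / 180))
    na_s <- gps_na[idx]
    lat_s[na_s] <- NA_real_
    lon_s[na_s] <- NA_real_
    traces[[id]] <- data.table::data.table(
      timestamp = ts, pm25 = pm25[idx], pm10 = pm10[idx],
      lat = lat_s, lon = lon_s
    )
    labels[[id]] <- data.table::data.table(
      child_id = id, minute_start = minute_start, true_label = lab
    )
  }
  list(traces = traces, labels = data.table::rbindlist(labels),
       met = met, seed = seed)
}

# commute path: fence edge to fence edge along the home-school bearing so a
# noiseless trace is never inside a fence during a true commute minute
commute_positions <- function(minute_start, lab, anc, config) {
  n <- length(lab)
  lat <- rep(anc$home_lat, n)
  lon <- rep(anc$home_lon, n)
  at_school <- lab == "school"
  lat[at_school] <- anc$school_lat
  lon[at_school] <- anc$school_lon
  cfgt <- list(home_radius_m = 100, school_radius_m = 100)
  sep <- dist_m(anc$home_lat, anc$home_lon, anc$school_lat, anc$school_lon)
  # unit vector home -> school in lat/lon space
  ulat <- (anc$school_lat - anc$home_lat) / sep
  ulon <- (anc$school_lon - anc$home_lon) / sep
  eps <- 5
  d0 <- cfgt$home_radius_m + eps
  d1 <- sep - cfgt$school_radius_m - eps
  if (d1 <= d0) { d0 <- sep * 0.45; d1 <- sep * 0.55 }
  cm <- which(lab == "commute")
  if (length(cm)) {
    runs <- split(cm, cumsum(c(1L, diff(cm) != 1L)))
    for (r in runs) {
      # direction: morning commute goes home -> school, afternoon reverse
      to_school <- as.integer(format(minute_start[r[1]], "%H")) <
        config$schedule$school[1]
      frac <- (seq_along(r) - 0.5) / length(r)
      d <- if (to_school) d0 + frac * (d1 - d0) else d1 - frac * (d1 - d0)
      lat[r] <- anc$home_lat + ulat * d
      lon[r] <- anc$home_lon + ulon * d
    }
  }
  list(lat = lat, lon = lon)
}

# alternating up/down segments; returns logical vector of dropout minutes
dropout_minutes <- function(n_min, config) {
  rate <- config$dropout_rate
  out <- rep(FALSE, n_min)
  if (rate <= 0) return(out)
  if (rate >= 1) return(rep(TRUE, n_min))
  mean_down <- config$dropout_mean_min
  mean_up <- mean_down * (1 - rate) / rate
  pos <- 1L
  up <- runif(1) > rate
  while (pos <= n_min) {
    len <- max(1L, round(rexp(1, 1 / if (up) mean_up else mean_down)))
    if (!up) out[pos:min(n_min, pos + len - 1L)] <- TRUE
    pos <- pos + len
    up <- !up
  }
  out
}

#' Score pipeline outputs against the generator's ground truth
#'
#' @param labeled_by_child Labelled minutes with `child_id` column.
#' @param truth_labels `labels` element from [generate_traces()].
#' @param fit Optional [fit_lmm()] result for effect-recovery scoring.
#' @param truth Optional truth list from [generate_cohort()] (needed for
#'   effect recovery and the seed consistency check).
#' @param seed Seed the outputs were produced from; checked against
#'   `truth$seed` when both are available.
#' @return List: `accuracy` (overall minute-level tagging accuracy),
#'   `per_child` accuracy table, and `effects` (planted vs estimated log
#'   effects with 95% CI coverage flags) when `fit` is supplied.
#' @export
score_against_truth <- function(labeled_by_child, truth_labels, fit = NULL,
                                truth = NULL, seed = NULL) {
  if (!is.null(truth) && !is.null(seed) && !identical(seed, truth$seed)) {
    stop("consistency error: outputs scored against a different seed's truth",
         call. = FALSE)
  }
  out <- list(accuracy = NA_real_, per_child = NULL, effects = NULL)
  if (!is.null(labeled_by_child) && !is.null(truth_labels)) {
    l <- data.table::as.data.table(labeled_by_child)
    j <- merge(l[, .(child_id, minute_start, label)],
               truth_labels, by = c("child_id", "minute_start"))
    out$accuracy <- mean(j$label == j$true_label)
    out$per_child <- j[, .(accuracy = mean(label == true_label)),
                       by = child_id]
  }
  if (!is.null(fit) && !is.null(truth)) {
    b <- fit$betas
    planted <- truth$effects_log
    hit <- b$term %in% names(planted)
    if (any(hit)) {
      bb <- b[hit]
      tr <- planted[bb$term]
      tcrit <- qt(0.975, bb$df)
      out$effects <- data.table::data.table(
        term = bb$term, planted_log = as.numeric(tr),
        estimated_log = bb$estimate, error = bb$estimate - as.numeric(tr),
        ci_cover = (bb$estimate - tcrit * bb$se <= tr) &
          (tr <= bb$estimate + tcrit * bb$se)
      )
    }
  }
  out
}
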