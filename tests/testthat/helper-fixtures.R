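# shared fixture builders -- everything constructed in code, no files

t0 <- function(h = 0, m = 0, day = "2021-09-06") {
  as.POSIXct(sprintf("%s %02d:%02d:00", day, h, m), tz = "UTC")
}

# minute-record table with direct control over validity flags
make_minutes <- function(n, start = t0(), pm25 = 10, pm10 = 20,
                         pm_valid = TRUE, gps_valid = TRUE,
                         lat = -15.7861, lon = 35.0058) {
  data.table::data.table(
    minute_start = start + 60 * (seq_len(n) - 1),
    pm25_mean = rep_len(pm25, n), pm10_mean = rep_len(pm10, n),
    lat = rep_len(lat, n), lon = rep_len(lon, n),
    n_samples_valid = ifelse(rep_len(pm_valid, n), 60L, 0L),
    pm_valid = rep_len(pm_valid, n), gps_valid = rep_len(gps_valid, n)
  )
}

write_toy_trace <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(c("timestamp,pm25,pm10,lat,lon", lines), path)
  path
}

# independent brute-force rank oracle for Kruskal-Wallis / Dunn:
# midranks computed by first principles (sorting + averaging), tie terms
# accumulated by explicit enumeration. Kept free of any package internals.
oracle_rank_tests <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  ord <- order(x)
  r <- numeric(N)
  i <- 1
  while (i <= N) {
    j <- i
    while (j < N && x[ord[j + 1]] == x[ord[i]]) j <- j + 1
    r[ord[i:j]] <- mean(i:j)
    i <- j + 1
  }
  g <- rep(seq_along(groups), lengths(groups))
  n <- lengths(groups)
  Rsum <- sapply(seq_along(groups), function(k) sum(r[g == k]))
  H <- 12 / (N * (N + 1)) * sum(Rsum^2 / n) - 3 * (N + 1)
  tie <- 0
  for (v in unique(x)) {
    t <- sum(x == v)
    tie <- tie + t^3 - t
  }
  C <- 1 - tie / (N^3 - N)
  H <- if (C > 0) H / C else 0
  rbar <- Rsum / n
  pairs <- utils::combn(length(groups), 2)
  z <- apply(pairs, 2, function(p) {
    se <- sqrt((N * (N + 1) / 12 - tie / (12 * (N - 1))) *
                 (1 / n[p[1]] + 1 / n[p[2]]))
    if (se > 0) (rbar[p[1]] - rbar[p[2]]) / se else 0
  })
  list(H = H, z = z)
}

# tiny generator configs for fast synthetic runs
small_gen_config <- function(n_cities = 2, n_children = 2,
                             resolution_s = 5) {
  g <- wearpm::default_generator_config()
  g$cities <- g$cities[seq_len(n_cities), , drop = FALSE]
  g$cities$n_children <- rep(as.integer(n_children), n_cities)
  g$resolution_s <- resolution_s
  g
}

# config whose minute-validity rule matches a coarser sampling cadence
config_for_resolution <- function(resolution_s) {
  cfg <- wearpm::default_config()
  cfg$generator$resolution_s <- resolution_s
  cfg$qc$minute_valid_min <- max(1L, (60 %/% resolution_s) %/% 2)
  cfg
}
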