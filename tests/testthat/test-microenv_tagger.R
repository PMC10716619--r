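home_pt <- c(-15.7861, 35.0058)
school_pt <- c(-15.7781, 35.0158)  # ~1.4 km away

toy_anchors <- function() {
  infer_anchors(NULL, NULL, home = home_pt, school = school_pt)
}

test_that("infer_anchors recovers a degenerate cluster exactly", {
  m <- make_minutes(36 * 60, start = t0(10), lat = home_pt[1],
                    lon = home_pt[2])
  # school window fixes at the school point
  hrs <- as.integer(format(m$minute_start, "%H"))
  m$lat[hrs >= 10 & hrs < 14] <- school_pt[1]
  m$lon[hrs >= 10 & hrs < 14] <- school_pt[2]
  a <- infer_anchors(m, school_days = as.Date("2021-09-06") + 0:1)
  expect_equal(a$home, home_pt, tolerance = 1e-9)
  expect_equal(a$school, school_pt, tolerance = 1e-9)
  expect_equal(a$provenance, "inferred")
})

test_that("infer_anchors centroid is within 15 m of truth under 30 m jitter", {
  set.seed(7)
  n <- 420
  jit <- function(pt, n) {
    list(lat = pt[1] + rnorm(n, 0, 30) / 111320,
         lon = pt[2] + rnorm(n, 0, 30) / (111320 * cos(pt[1] * pi / 180)))
  }
  hj <- jit(home_pt, n)
  # overnight window 22:00-05:00 across two nights
  m <- make_minutes(n, start = t0(22), lat = hj$lat, lon = hj$lon)
  sj <- jit(school_pt, 240)
  ms <- make_minutes(240, start = t0(10, day = "2021-09-07"),
                     lat = sj$lat, lon = sj$lon)
  a <- infer_anchors(rbind(m, ms), school_days = as.Date("2021-09-07"))
  # oracle: direct centroid of the generating cluster
  oracle <- c(mean(hj$lat), mean(hj$lon))
  expect_lt(dist_m(a$home[1], a$home[2], home_pt[1], home_pt[2]), 15)
  expect_lt(dist_m(a$home[1], a$home[2], oracle[1], oracle[2]), 15)
})

test_that("infer_anchors errors on insufficient fixes and close anchors", {
  m <- make_minutes(120, start = t0(12))  # no overnight fixes
  expect_error(infer_anchors(m, school_days = as.Date("2021-09-06")),
               "anchor-inference error")
  expect_error(
    infer_anchors(NULL, NULL, home = home_pt,
                  school = home_pt + c(0.0003, 0)),  # ~33 m apart
    "anchor-conflict")
})

test_that("tag_minutes applies fence, transition and carry-forward rules", {
  a <- toy_anchors()
  cfg <- default_config()
  # 20 m from home anchor -> home via geofence
  m <- make_minutes(1, lat = home_pt[1] + 20 / 111320, lon = home_pt[2])
  l <- tag_minutes(m, a, cfg)
  expect_equal(l$label, "home")
  expect_equal(l$label_source, "geofence")

  # home minutes, 25-min gap en route, then school -> commute via transition
  mid <- c(mean(c(home_pt[1], school_pt[1])), mean(c(home_pt[2], school_pt[2])))
  seqm <- rbind(
    make_minutes(10, start = t0(7, 0), lat = home_pt[1], lon = home_pt[2]),
    make_minutes(25, start = t0(7, 10), lat = mid[1], lon = mid[2]),
    make_minutes(10, start = t0(7, 35), lat = school_pt[1], lon = school_pt[2])
  )
  l2 <- tag_minutes(seqm, a, cfg)
  expect_equal(unique(l2$label[11:35]), "commute")
  expect_equal(unique(l2$label_source[11:35]), "transition")

  # beyond the commute window the same shape becomes "other"
  seqm3 <- rbind(
    make_minutes(10, start = t0(6, 0), lat = home_pt[1], lon = home_pt[2]),
    make_minutes(150, start = t0(6, 10), lat = mid[1], lon = mid[2]),
    make_minutes(10, start = t0(8, 40), lat = school_pt[1], lon = school_pt[2])
  )
  l3 <- tag_minutes(seqm3, a, cfg)
  expect_equal(unique(l3$label[11:160]), "other")

  # 90 GPS-invalid minutes after school: 60 carried forward, 30 unknown
  seqm4 <- rbind(
    make_minutes(10, start = t0(13, 0), lat = school_pt[1], lon = school_pt[2]),
    make_minutes(90, start = t0(13, 10), gps_valid = FALSE,
                 lat = NA_real_, lon = NA_real_)
  )
  l4 <- tag_minutes(seqm4, a, cfg)
  expect_equal(l4$label[11:70], rep("school", 60))
  expect_equal(unique(l4$label_source[11:70]), "carry_forward")
  expect_equal(l4$label[71:100], rep("unknown", 30))
  expect_equal(unique(l4$label_source[71:100]), "none")
})

test_that("every minute gets exactly one label; unknown <=> source none", {
  set.seed(13)
  a <- toy_anchors()
  n <- 600
  m <- make_minutes(n, start = t0(6),
                    lat = home_pt[1] + rnorm(n, 0, 0.004),
                    lon = home_pt[2] + rnorm(n, 0, 0.004),
                    gps_valid = runif(n) > 0.2)
  m$lat[!m$gps_valid] <- NA
  m$lon[!m$gps_valid] <- NA
  l <- tag_minutes(m, a)
  expect_false(any(is.na(l$label)))
  expect_true(all(l$label %in% c("home", "school", "commute", "other",
                                 "unknown")))
  expect_equal(l$label == "unknown", l$label_source == "none")
})

test_that("shrinking radii only moves minutes out of home/school", {
  set.seed(17)
  n <- 400
  m <- make_minutes(n, start = t0(6),
                    lat = home_pt[1] + rnorm(n, 0, 0.002),
                    lon = home_pt[2] + rnorm(n, 0, 0.002))
  big <- infer_anchors(NULL, NULL, home = home_pt, school = school_pt)
  small <- big
  small$home_radius_m <- 50
  small$school_radius_m <- 50
  lb <- tag_minutes(m, big)
  ls <- tag_minutes(m, small)
  was_home <- lb$label == "home"
  expect_true(all(ls$label[!was_home & lb$label == "school"] != "home"))
  # no minute may switch between home and school
  expect_false(any(was_home & ls$label == "school"))
  expect_false(any(lb$label == "school" & ls$label == "home"))
  # minutes inside the small fence stay put
  expect_true(all(ls$label[ls$label == "home"] == lb$label[ls$label == "home"]))
})

test_that("tag_summary counts labels exhaustively", {
  a <- toy_anchors()
  m <- rbind(
    make_minutes(100, start = t0(0), lat = home_pt[1], lon = home_pt[2]),
    make_minutes(50, start = t0(2), lat = school_pt[1], lon = school_pt[2])
  )
  l <- tag_minutes(m, a)
  s <- tag_summary(l)
  expect_equal(unname(s["home"]), 100L)
  expect_equal(unname(s["school"]), 50L)
  expect_equal(sum(s), nrow(m))
  expect_equal(sum(tag_summary(l[0])), 0L)
})
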