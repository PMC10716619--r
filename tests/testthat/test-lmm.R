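balanced_toy <- function(seed = 42, m = 4, nc = 5, nd = 4,
                         s_city = 0.3, s_child = 0.4, s_e = 0.25) {
  set.seed(seed)
  d <- data.table::CJ(city_id = sprintf("city%02d", 1:m), ch = 1:nc,
                      day = 1:nd)
  d[, child_id := paste(city_id, ch, sep = "_")]
  u_city <- stats::setNames(rnorm(m, 0, s_city), unique(d$city_id))
  u_child <- stats::setNames(rnorm(m * nc, 0, s_child), unique(d$child_id))
  d[, pm25_daily_mean := exp(3 + u_city[city_id] + u_child[child_id] +
                               rnorm(.N, 0, s_e))]
  d
}

# closed-form ANOVA estimator for the balanced two-level nested design
nested_anova_oracle <- function(d) {
  ly <- log(d$pm25_daily_mean)
  m <- length(unique(d$city_id))
  nc <- length(unique(d$child_id)) / m
  nd <- nrow(d) / (m * nc)
  cm <- tapply(ly, d$city_id, mean)
  chm <- tapply(ly, d$child_id, mean)
  gm <- mean(ly)
  city_of_child <- tapply(d$city_id, d$child_id, `[`, 1)
  ms_city <- nd * nc * sum((cm - gm)^2) / (m - 1)
  ms_child <- nd * sum((chm - cm[city_of_child])^2) / (m * (nc - 1))
  ms_e <- sum((ly - chm[d$child_id])^2) / (m * nc * (nd - 1))
  c(city = (ms_city - ms_child) / (nd * nc),
    child = (ms_child - ms_e) / nd,
    resid = ms_e)
}

test_that("REML variance components match the balanced nested ANOVA oracle", {
  # seeds chosen so the ANOVA solution is interior (all components > 0),
  # where REML and the closed form coincide for balanced designs
  seeds <- Filter(function(s) min(nested_anova_oracle(balanced_toy(s))) > 0.01,
                  41:50)[1:3]
  for (seed in seeds) {
    d <- balanced_toy(seed)
    fit <- fit_lmm(d, character(0))
    oracle <- nested_anova_oracle(d)
    expect_gt(min(oracle), 0)  # interior solution required for equality
    expect_lt(abs(fit$sigma2_location - oracle["city"]), 1e-6)
    expect_lt(abs(fit$sigma2_child - oracle["child"]), 1e-6)
    expect_lt(abs(fit$sigma2_resid - oracle["resid"]), 1e-6)
    # intercept mean equals the grand mean in a balanced design
    expect_equal(fit$alpha, mean(log(d$pm25_daily_mean)), tolerance = 1e-6)
  }
})

test_that("Satterthwaite df reproduce the classical balanced-design df", {
  d <- balanced_toy(45)
  fit <- fit_lmm(d, character(0))
  expect_equal(fit$ddf_method, "satterthwaite")
  # intercept variance is dominated by the 4 city means: df ~ m - 1 = 3
  # (recover df from the reported model internals via a refit with a
  # city-level covariate as a cross-check below)
  d$grp <- factor(ifelse(as.integer(factor(d$city_id)) <= 2, "A", "B"))
  fit2 <- fit_lmm(d, "grp")
  expect_lt(fit2$betas$df, 10)   # city-level contrast: about m - 2 df
  expect_gt(fit2$betas$df, 0.5)
  # day-level covariate gets far larger df
  set.seed(9)
  d$xday <- rnorm(nrow(d))
  fit3 <- fit_lmm(d, "xday")
  expect_gt(fit3$betas$df[fit3$betas$term == "xday"], 30)
})

test_that("degenerate and singular designs are handled explicitly", {
  d <- data.table::data.table(city_id = "a", child_id = rep(c("c1", "c2"), 4),
                              pm25_daily_mean = 10)
  f <- fit_lmm(d, character(0))
  expect_equal(f$alpha, log(10))
  expect_equal(f$sigma2_location, 0)
  expect_equal(f$sigma2_child, 0)
  expect_equal(f$sigma2_resid, 0)
  expect_equal(f$status, "degenerate")

  d2 <- balanced_toy(46)
  d2$dup <- d2$day          # exactly collinear with 'day' after centering
  expect_error(fit_lmm(d2, c("day", "dup")), "aliased")

  d3 <- balanced_toy(47)
  d3$pm25_daily_mean[1] <- -1
  expect_error(fit_lmm(d3, character(0)), "strictly positive")
})

test_that("planted smoking effect is recovered on one full-size cohort", {
  g <- default_generator_config()
  g$cities$n_children <- c(24L, 48L, 43L, 62L, 62L, 61L)  # 300 children
  cg <- generate_cohort(g, seed = 1)
  daily <- generate_daily_exposures(cg$cohort, cg$truth, g, seed = 1)
  mdl <- merge(daily, cg$cohort, by = c("child_id", "city_id"))
  mdl <- merge(mdl, attr(daily, "met"), by = c("city_id", "date"))
  fit <- fit_lmm(mdl, c("smoking_at_home", "cooker_type", "lighting_use",
                        "school_ground_surface", "commute_mode",
                        "temp_c", "wind_ms"))
  sm <- fit$betas[fit$betas$term == "smoking_at_homePresence of smokers", ]
  pct <- percent_change(sm$estimate, sm$se, sm$df)
  planted_log <- unname(cg$truth$effects_log[
    "smoking_at_homePresence of smokers"])
  planted_pct <- (exp(planted_log) - 1) * 100
  # one realisation: estimate within 2 SE of the planted effect (the
  # calibration criterion checks coverage over 200 cohorts)
  expect_lt(abs(sm$estimate - planted_log), 2 * sm$se)
  expect_lt(pct$ci_low, planted_pct)
  expect_gt(pct$ci_high, planted_pct)
  expect_equal(sm$reference, "No smokers")
})

test_that("percent change is invariant to city relabelling", {
  d <- balanced_toy(48)
  set.seed(10)
  d$x <- stats::setNames(rnorm(20), unique(d$child_id))[d$child_id]
  f1 <- fit_lmm(d, "x")
  d2 <- data.table::copy(d)
  d2$city_id <- factor(d2$city_id,
                       labels = rev(sprintf("relabel%02d", 1:4)))
  f2 <- fit_lmm(d2, "x")
  expect_equal(f1$betas$estimate, f2$betas$estimate, tolerance = 1e-8)
  m1 <- merge(f1$betas, f1$percent_changes, by = "term")
  m2 <- merge(f2$betas, f2$percent_changes, by = "term")
  expect_equal(m1$pct_change, m2$pct_change, tolerance = 1e-6)
})
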