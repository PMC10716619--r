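#' Published six-city reference counts
#'
#' Per-city child and valid-day counts, and whole-study WHO-guideline
#' compliant-day counts, as printed in the six-city campaign this package's
#' defaults are calibrated to. Used for arithmetic cross-checks of the
#' characteristics-table machinery (overall column = sum of city columns;
#' compliance percentage = compliant days / total days).
#'
#' @return List with elements `cities` (`city_id, children_monitored,
#'   days_monitored`) and `guideline` (`pollutant, days_below_guideline`).
#' @export
reference_counts <- function() {
  dir <- system.file("extdata", package = "wearpm")
  list(
    cities = data.table::fread(file.path(dir, "sixcity_reference.csv")),
    guideline = data.table::fread(file.path(dir,
                                            "sixcity_guideline_reference.csv"))
  )
}

#' Cohort characteristics table
#'
#' Per-city and overall summaries in the style of a study characteristics
#' table: child and valid-day counts, determinant level counts with
#' percentages (of child-days, rounded to integer percent), and daily PM2.5
#' exposure summaries (median, arithmetic mean, geometric mean; 1 decimal
#' place). The overall column is the sum for counts and the pooled statistic
#' for exposures.
#'
#' @param cohort Cohort table.
#' @param daily Stacked [daily_means()] rows with `child_id`.
#' @param ledger Optional exclusion ledger; when given, only included
#'   children are summarised.
#' @return Long-format `data.table` `section, level, city_id, value`, with
#'   `city_id = "All"` rows for the overall column.
#' @export
cohort_table <- function(cohort, daily, ledger = NULL) {
  co <- data.table::as.data.table(cohort)
  d <- data.table::as.data.table(daily)
  if (!is.null(ledger)) {
    inc <- ledger$child_id[ledger$status == "included"]
    co <- co[child_id %in% inc]
    d <- d[child_id %in% inc]
  }
  if (nrow(co) == 0) {
    return(data.table::data.table(section = character(), level = character(),
                                  city_id = character(), value = numeric()))
  }
  d <- merge(d, co[, .(child_id, city_id)], by = "child_id",
             suffixes = c("", ".co"))
  if ("city_id.co" %in% names(d)) d[, city_id := NULL][
    , city_id := city_id.co][, city_id.co := NULL]
  cities <- sort(unique(co$city_id))
  rows <- list()
  add <- function(section, level, city, value) {
    rows[[length(rows) + 1]] <<- data.table::data.table(
      section = section, level = level, city_id = city, value = value)
  }
  nch <- d[, .(n = data.table::uniqueN(child_id)), by = city_id]
  nda <- d[, .N, by = city_id]
  for (ci in cities) {
    add("children_monitored", "", ci, nch$n[match(ci, nch$city_id)] %||na% 0)
    add("days_monitored", "", ci, nda$N[match(ci, nda$city_id)] %||na% 0)
  }
  add("children_monitored", "", "All", sum(nch$n))
  add("days_monitored", "", "All", sum(nda$N))
  # determinant level counts as child-days (denominator: days monitored)
  dl <- determinant_levels()
  dd <- merge(d[, .(child_id, city_id)], co, by = c("child_id", "city_id"))
  for (det in names(dl)) {
    for (lv in dl[[det]]) {
      cnt_city <- dd[, sum(get(det) == lv), by = city_id]
      for (ci in cities) {
        v <- cnt_city$V1[match(ci, cnt_city$city_id)] %||na% 0
        add(paste0(det, "_n"), lv, ci, v)
        denom <- nda$N[match(ci, nda$city_id)] %||na% 0
        add(paste0(det, "_pct"), lv, ci,
            if (denom > 0) round(100 * v / denom) else NA_real_)
      }
      add(paste0(det, "_n"), lv, "All", sum(cnt_city$V1))
      add(paste0(det, "_pct"), lv, "All",
          if (sum(nda$N) > 0) round(100 * sum(cnt_city$V1) / sum(nda$N))
          else NA_real_)
    }
  }
  gm <- function(x) exp(mean(log(x)))
  for (ci in c(cities, "All")) {
    x <- if (ci == "All") d$pm25_daily_mean else
      d$pm25_daily_mean[d$city_id == ci]
    if (!length(x)) next
    add("pm25_daily_median", "", ci, round(median(x), 1))
    add("pm25_daily_mean", "", ci, round(mean(x), 1))
    add("pm25_daily_gm", "", ci, round(gm(x), 1))
    add("pm25_daily_gsd", "", ci, round(exp(sd(log(x))), 1))
  }
  data.table::rbindlist(rows)
}

`%||na%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' Run the full pipeline on a synthetic cohort
#'
#' Executes generation, minute aggregation, validity screening, anchor
#' inference and tagging, exposure summarisation and the determinants model
#' in order, writing every output table plus `manifest.json` under
#' `out_dir`. A stage failure stops the run with the stage name (and child
#' context where applicable); tables from completed stages remain on disk.
#'
#' @param config Full configuration, see [default_config()].
#' @param out_dir Output directory.
#' @param seed Integer seed driving the generator.
#' @param force Overwrite existing outputs.
#' @param model_terms Fixed-effect terms for the determinants model; default
#'   uses every determinant with at least two observed levels plus
#'   meteorology and day of week.
#' @param input_dir Optional directory with pre-existing inputs
#'   (`cohort.csv`, `meteorology.csv`, `traces/<child_id>.csv`); when `NULL`
#'   (default) a synthetic cohort is generated from `config$generator` and
#'   scored against its ground truth.
#' @return Invisibly, a list with the main in-memory results
#'   (`cohort`, `ledger`, `daily`, `microenv`, `diurnal`, `compliance`,
#'   `fit`, `scorecard`, `manifest`).
#' @export
run_pipeline <- function(config = default_config(), out_dir, seed = 1,
                         force = FALSE, model_terms = NULL,
                         input_dir = NULL) {
  g <- config$generator
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  gen <- if (is.null(input_dir)) {
    stage("generate", {
      cg <- generate_cohort(g, seed)
      tr <- generate_traces(cg$cohort, cg$truth, g, seed)
      list(cohort = cg$cohort, truth = cg$truth, traces = tr)
    })
  } else {
    stage("inputs", {
      tdir <- file.path(input_dir, "traces")
      for (pth in c(input_dir, file.path(input_dir, "cohort.csv"),
                    file.path(input_dir, "meteorology.csv"), tdir)) {
        if (!file.exists(pth)) {
          stop("input not resolvable: ", pth, call. = FALSE)
        }
      }
      cohort <- read_cohort(file.path(input_dir, "cohort.csv"), config)
      met <- read_meteorology(file.path(input_dir, "meteorology.csv"))
      files <- list.files(tdir, pattern = "\\.csv$", full.names = TRUE)
      traces <- lapply(files, read_trace, config = config)
      names(traces) <- tools::file_path_sans_ext(basename(files))
      list(cohort = cohort, truth = NULL,
           traces = list(traces = traces, met = met, labels = NULL))
    })
  }
  cohort <- gen$cohort
  write_outputs(list(cohort = cohort), out_dir, force = force)

  minutes <- stage("aggregate", {
    lapply(gen$traces$traces, aggregate_minutes, config = config)
  })
  validity <- stage("qc", {
    data.table::rbindlist(lapply(names(minutes), function(id) {
      validity_report(minutes[[id]], id, config)
    }))
  })
  anchor_override <- NULL
  if (!is.null(input_dir) &&
        file.exists(file.path(input_dir, "anchors.json"))) {
    anchor_override <- jsonlite::read_json(
      file.path(input_dir, "anchors.json"), simplifyVector = TRUE)
  }
  labeled <- stage("tag", {
    out <- list()
    for (id in names(minutes)) {
      dts <- unique(as.Date(minutes[[id]]$minute_start))
      school_days <- dts[!weekdays(dts) %in% c("Saturday", "Sunday")]
      ov <- anchor_override[[id]]
      anc <- tryCatch(
        infer_anchors(minutes[[id]], school_days, config,
                      home = ov$home, school = ov$school),
        error = function(e) NULL)
      if (is.null(anc)) next
      l <- tag_minutes(minutes[[id]], anc, config)
      l[, child_id := id]
      out[[id]] <- l
    }
    out
  })
  tagsum <- data.table::rbindlist(lapply(names(labeled), function(id) {
    s <- tag_summary(labeled[[id]])
    data.table::data.table(child_id = id, school_minutes = s[["school"]])
  }))
  ledger <- stage("ledger", {
    build_exclusion_ledger(cohort, questionnaires = cohort$child_id,
                           validity_reports = validity,
                           tag_summaries = tagsum)
  })
  write_outputs(list(validity_report = validity, exclusion_ledger = ledger),
                out_dir, force = force)

  included <- ledger$child_id[ledger$status == "included"]
  daily <- stage("metrics", {
    out <- suppressMessages(data.table::rbindlist(
      lapply(intersect(included, names(labeled)), function(id) {
        daily_means(labeled[[id]], id, config)
      })))
    if (ncol(out) == 0) out <- daily_means(NULL)
    out
  })
  microenv <- stage("metrics", {
    data.table::rbindlist(lapply(intersect(included, names(labeled)),
      function(id) {
        gap <- validity$gps_gap_over_12h[match(id, validity$child_id)]
        microenv_summaries(labeled[[id]], id, gap, config)
      }))
  })
  lab_all <- data.table::rbindlist(labeled)
  diurnal <- stage("metrics", {
    diurnal_profiles(lab_all[child_id %in% included],
                     cohort[, c("child_id", "city_id")])
  })
  compliance <- stage("metrics", guideline_compliance(daily, config))
  chars <- stage("metrics", cohort_table(cohort, daily, ledger))
  write_outputs(list(
    labeled_minutes = lab_all,
    daily_exposure = daily, microenv_summary = microenv,
    diurnal_profile = diurnal,
    compliance = data.table::as.data.table(compliance),
    characteristics_table = chars
  ), out_dir, force = force)

  group_tests <- stage("inference", {
    dd <- merge(daily, cohort[, c("child_id", "city_id")], by = "child_id")
    out <- list()
    if (nrow(dd) && length(unique(dd$city_id)) >= 2) {
      grp <- split(dd$pm25_daily_mean, dd$city_id)
      kw <- kruskal_wallis(grp)
      dn <- dunn_posthoc(grp)
      out$city <- data.table::data.table(
        family = "daily_pm25_by_city", H = kw$H, df = kw$df, p = kw$p,
        dn)
    }
    me <- microenv[!is.na(microenv$pm25_mean) &
                     microenv$label %in% c("home", "school", "commute"), ]
    if (nrow(me) && length(unique(me$label)) >= 2) {
      grp <- split(me$pm25_mean, me$label)
      kw <- kruskal_wallis(grp)
      dn <- dunn_posthoc(grp)
      out$micro <- data.table::data.table(
        family = "child_mean_pm25_by_microenv", H = kw$H, df = kw$df,
        p = kw$p, dn)
    }
    data.table::rbindlist(out)
  })
  if (nrow(group_tests)) {
    write_outputs(list(group_tests = group_tests), out_dir, force = force)
  }

  fit <- stage("model", {
    met <- gen$traces$met
    mdl <- merge(daily, cohort, by = "child_id")
    mdl <- merge(mdl, met, by = c("city_id", "date"))
    mdl$day_of_week <- factor(mdl$day_of_week,
                              levels = intersect(
                                c("Monday", "Tuesday", "Wednesday", "Thursday"),
                                unique(mdl$day_of_week)))
    if (is.null(model_terms)) {
      cand <- c(names(determinant_levels()), "day_of_week",
                "temp_c", "rh_pct", "wind_ms")
      cand <- Filter(function(tm) {
        v <- mdl[[tm]]
        if (is.numeric(v)) var(v) > 0 else
          length(unique(as.character(v[!is.na(v)]))) >= 2
      }, cand)
      model_terms <- prune_aliased_terms(mdl, cand)
    }
    if (nrow(mdl) >= 20 && length(unique(mdl$city_id)) >= 2) {
      fit_lmm(mdl, model_terms)
    } else NULL
  })
  if (!is.null(fit)) {
    tab <- merge(fit$betas, fit$percent_changes, by = "term", sort = FALSE)
    write_outputs(list(determinants_model = tab), out_dir, force = force)
    # collinearity diagnostics on the fitted design (minus intercept)
    diag_tab <- stage("diagnostics", {
      Xf <- fit$design
      if (!is.null(Xf) && ncol(Xf) > 2) {
        v <- tryCatch(vif(Xf[, -1, drop = FALSE]), error = function(e) NULL)
        if (!is.null(v)) {
          data.table::data.table(column = names(v), vif = as.numeric(v),
                                 max_vif = max(v))
        } else NULL
      } else NULL
    })
    if (!is.null(diag_tab)) {
      write_outputs(list(diagnostics = diag_tab), out_dir, force = force)
    }
  }
  scorecard <- if (is.null(gen$truth)) NULL else
    score_against_truth(lab_all, gen$traces$labels, fit, gen$truth,
                        seed = seed)

  manifest <- list(
    package = "wearpm",
    version = as.character(utils::packageVersion("wearpm")),
    seed = seed,
    config_hash = unname(config_hash(config)),
    outputs = list.files(out_dir, pattern = "\\.csv$"),
    finished = format_ts(Sys.time())
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(cohort = cohort, truth = gen$truth, validity = validity,
                 ledger = ledger, daily = daily, microenv = microenv,
                 diurnal = diurnal, compliance = compliance,
                 characteristics = chars, fit = fit, scorecard = scorecard,
                 manifest = manifest))
}

# greedily keep terms whose design columns stay full rank (small synthetic
# cohorts cannot identify the full questionnaire determinant set)
prune_aliased_terms <- function(data, terms) {
  dl <- determinant_levels()
  df <- as.data.frame(data)
  for (d in intersect(names(dl), terms)) {
    lv <- intersect(dl[[d]], unique(as.character(df[[d]])))
    df[[d]] <- factor(as.character(df[[d]]), levels = lv)
  }
  kept <- character()
  for (tm in terms) {
    trial <- c(kept, tm)
    X <- model.matrix(as.formula(paste("~", paste(trial, collapse = " + "))),
                      df)
    if (qr(X)$rank == ncol(X)) kept <- trial
  }
  kept
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  tools::md5sum(tmp)
}

#' Command-line entry point
#'
#' Subcommands: `generate` (emit a synthetic input set), `run` (full
#' pipeline), `report` (characteristics table from a previous run's outputs).
#' Flags: `--config <json>`, `--seed <int>`, `--out <dir>`, `--force`.
#'
#' @param args Character vector of CLI arguments (default: the process
#'   command line).
#' @return Exit status 0 invisibly on success.
#' @export
wearpm_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: wearpm <generate|run> --out DIR [--config FILE] [--seed N] [--force]"
  if (!length(args)) stop(usage, call. = FALSE)
  cmd <- args[1]
  opt <- list(config = NULL, seed = 1L, out = NULL, force = FALSE,
              "in" = NULL)
  i <- 2
  while (i <= length(args)) {
    a <- args[i]
    if (a == "--force") { opt$force <- TRUE; i <- i + 1; next }
    if (!a %in% c("--config", "--seed", "--out", "--in") ||
        i == length(args)) {
      stop(usage, call. = FALSE)
    }
    opt[[sub("^--", "", a)]] <- args[i + 1]
    i <- i + 2
  }
  if (is.null(opt$out)) stop(usage, call. = FALSE)
  cfg <- if (is.null(opt$config)) default_config() else read_config(opt$config)
  seed <- as.integer(opt$seed)
  if (cmd == "generate") {
    cg <- generate_cohort(cfg$generator, seed)
    tr <- generate_traces(cg$cohort, cg$truth, cfg$generator, seed)
    dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
    write_outputs(list(cohort = cg$cohort, meteorology = tr$met,
                       true_labels = tr$labels),
                  opt$out, force = opt$force)
    tdir <- file.path(opt$out, "traces")
    dir.create(tdir, showWarnings = FALSE)
    for (id in names(tr$traces)) {
      write_trace(tr$traces[[id]], file.path(tdir, paste0(id, ".csv")))
    }
    jsonlite::write_json(
      list(seed = seed, gps_gap_children = cg$truth$gps_gap_children),
      file.path(opt$out, "truth.json"), auto_unbox = TRUE, pretty = TRUE)
  } else if (cmd == "run") {
    run_pipeline(cfg, opt$out, seed = seed, force = opt$force,
                 input_dir = opt[["in"]])
  } else {
    stop(usage, call. = FALSE)
  }
  invisible(0L)
}
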