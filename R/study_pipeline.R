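# End-to-end study pipeline: pairing local and central stages, overall /
# per-laboratory / per-LIMS agreement, sensitivity and subgroup analyses,
# descriptive tables, and the report bundle.

#' Build stage pairs for every evaluable creatinine result
#'
#' One pair per result whose local stage is evaluable: the local stage comes
#' from [infer_local_stage()] (a received alert, or an inferred 0 after the
#' laboratory live date), the central stage from [run_central_algorithm()].
#' Covariates for subgrouping are attached: `baseline_scr` (RV2 when
#' present, else RV1), `age_at_test` in completed years, and calendar
#' `year`.
#'
#' @param x `aki_cohort`
#' @param central optional precomputed engine output
#' @param live_dates optional precomputed [determine_live_dates()] table
#' @param config [akival_config()]
#' @return `data.table`: `mpi`, `lab_code`, `specimen_dt`, `c1`,
#'   `local_stage`, `central_stage`, `inferred`, `baseline_scr`,
#'   `age_at_test`, `year`
#' @export
build_pairs <- function(x, central = NULL, live_dates = NULL,
                        config = akival_config()) {
  stopifnot(inherits(x, "aki_cohort"))
  if (is.null(central)) central <- run_central_algorithm(x, config)
  if (is.null(live_dates)) live_dates <- determine_live_dates(x$alerts)
  loc <- infer_local_stage(x, live_dates, config = config)

  res <- copy(x$results)
  setorder(res, mpi, specimen_dt, scr)
  cen <- as.data.table(central)
  setorder(cen, mpi, specimen_dt, c1)
  stopifnot(nrow(res) == nrow(cen), nrow(res) == nrow(loc))

  pairs <- data.table(
    mpi = res$mpi, lab_code = res$lab_code, specimen_dt = res$specimen_dt,
    c1 = res$scr,
    local_stage = loc$local_stage,
    central_stage = as.integer(cen$stage),
    inferred = loc$inferred,
    baseline_scr = fifelse(!is.na(cen$rv2), cen$rv2, cen$rv1),
    age_at_test = whole_years(res$dob, res$specimen_dt),
    year = as.integer(format(res$specimen_dt, "%Y")))
  pairs[!is.na(local_stage)]
}

# one summary row for a set of pairs
agreement_row <- function(pairs, weights = "ordinal", conf_level = 0.95) {
  cm <- cross_tabulate(pairs$local_stage, pairs$central_stage)
  ag <- gwet_ac1(cm, weights = weights, conf_level = conf_level)
  ppa <- percent_positive_agreement(cm, weights = weights)
  data.table(n_pairs = nrow(pairs),
             n_lab_alerts = sum(pairs$local_stage > 0),
             n_central_alerts = sum(pairs$central_stage > 0),
             ppa = ppa$unweighted, ppa_weighted = ppa$weighted,
             coefficient = ag$coefficient, se = ag$se,
             ci_lower = ag$ci[1], ci_upper = ag$ci[2],
             band = ag$band)
}

#' Pooled cross-tabulation and agreement
#'
#' @param pairs from [build_pairs()]
#' @param config [akival_config()] (weight family and confidence level are
#'   taken from its `agreement` block)
#' @return list with `matrix` (`aki_confusion`) and `agreement`
#'   (`agreement_result`)
#' @export
overall_analysis <- function(pairs, config = akival_config()) {
  if (nrow(pairs) == 0) stop("no pairs to analyse")
  cm <- cross_tabulate(pairs$local_stage, pairs$central_stage)
  list(matrix = cm,
       agreement = gwet_ac1(cm, weights = config$agreement$weights,
                            conf_level = config$agreement$conf_level))
}

#' Agreement per laboratory, LIMS provider, or calendar year
#'
#' Laboratories missing from the LIMS map are pooled into a single
#' `"Unknown"` provider group rather than dropped. Rows are sorted in
#' ascending order of the coefficient, the convention for spotting outlying
#' laboratories.
#'
#' @param pairs from [build_pairs()]
#' @param by `"lab"`, `"lims"`, or `"year"`
#' @param lims_map `lab_code`/`lims_provider` table (required for
#'   `by = "lims"`)
#' @param config [akival_config()]
#' @return `data.table`, one row per group with pair/alert counts, percent
#'   positive agreement, coefficient, CI and band
#' @export
per_group_analysis <- function(pairs, by = c("lab", "lims", "year"),
                               lims_map = NULL, config = akival_config()) {
  by <- match.arg(by)
  p <- copy(pairs)
  if (by == "lab") {
    p[, group := lab_code]
  } else if (by == "year") {
    p[, group := as.character(year)]
  } else {
    lm <- if (!is.null(lims_map)) as.data.table(lims_map) else
      data.table(lab_code = character(), lims_provider = character())
    p <- lm[p, on = "lab_code"]
    p[, group := fifelse(is.na(lims_provider), "Unknown", lims_provider)]
  }
  out <- p[, agreement_row(.SD, config$agreement$weights,
                           config$agreement$conf_level), by = group]
  setorder(out, coefficient)
  out[]
}

#' Complete-case sensitivity analysis
#'
#' Drops pairs whose local stage-0 was merely inferred from the absence of
#' an alert (suppression or failed submission are competing explanations),
#' keeping all four stage categories, and recomputes agreement on the
#' remainder.
#'
#' @param pairs from [build_pairs()]
#' @param config [akival_config()]
#' @return `agreement_result`
#' @export
sensitivity_complete_case <- function(pairs, config = akival_config()) {
  sub <- pairs[inferred == FALSE]
  if (nrow(sub) == 0) stop("no pairs remain after dropping inferred zeros")
  cm <- cross_tabulate(sub$local_stage, sub$central_stage)
  gwet_ac1(cm, weights = config$agreement$weights,
           conf_level = config$agreement$conf_level)
}

#' Complete-months sensitivity analysis
#'
#' Restricts to laboratories whose every calendar month in span has both
#' creatinine and alert data (see [assess_monthly_completeness()]) and
#' recomputes agreement.
#'
#' @param pairs from [build_pairs()]
#' @param completeness flag table from [assess_monthly_completeness()] or a
#'   `lab_code`/`complete` summary from [lab_completeness()]
#' @param config [akival_config()]
#' @return list with `agreement` (`agreement_result`), `labs_kept`,
#'   `labs_dropped`
#' @export
sensitivity_complete_months <- function(pairs, completeness,
                                        config = akival_config()) {
  comp <- as.data.table(completeness)
  if (!"complete" %in% names(comp)) comp <- lab_completeness(comp)
  keep_labs <- comp[complete == TRUE, lab_code]
  sub <- pairs[lab_code %in% keep_labs]
  if (nrow(sub) == 0) stop("no pairs remain after the complete-months filter")
  cm <- cross_tabulate(sub$local_stage, sub$central_stage)
  list(agreement = gwet_ac1(cm, weights = config$agreement$weights,
                            conf_level = config$agreement$conf_level),
       labs_kept = keep_labs,
       labs_dropped = setdiff(unique(pairs$lab_code), keep_labs))
}

#' Subgroup agreement over baseline creatinine or age strata
#'
#' Cut-points are empirical quantiles of the pairs themselves (quartiles of
#' baseline creatinine, quintiles of age, by default); ties at a cut-point
#' fall into the lower stratum. Pairs missing the covariate are dropped with
#' a message. Alongside each stratum's coefficient the stage distribution
#' (percent per stage, local vs central) is reported, which is where
#' stage-3 under-reporting at high baselines shows up.
#'
#' @param pairs from [build_pairs()]
#' @param axis `"baseline_scr"` or `"age"`
#' @param n_groups number of strata; defaults to 4 for baseline creatinine
#'   and 5 for age
#' @param config [akival_config()]
#' @return list: `results` (per-stratum agreement rows), `stage_distribution`
#'   (per-stratum stage percents), `cutpoints`
#' @export
subgroup_analysis <- function(pairs, axis = c("baseline_scr", "age"),
                              n_groups = NULL, config = akival_config()) {
  axis <- match.arg(axis)
  if (is.null(n_groups)) n_groups <- if (axis == "baseline_scr") 4L else 5L
  x <- if (axis == "baseline_scr") pairs$baseline_scr else pairs$age_at_test
  ok <- !is.na(x)
  if (!all(ok)) message(sum(!ok), " pairs lack ", axis, "; dropped from subgrouping")
  p <- pairs[ok]
  x <- x[ok]
  if (nrow(p) < 2 * n_groups) warning("too few pairs for ", n_groups, " strata")
  qs <- unique(quantile(x, probs = seq(0, 1, length.out = n_groups + 1),
                        type = 7, names = FALSE))
  if (length(qs) < n_groups + 1) {
    warning("degenerate quantile cut-points; using ", length(qs) - 1, " strata")
  }
  if (length(qs) < 2) {
    warning("covariate is constant; single stratum")
    p[, stratum := factor("Q1")]
  } else {
    p[, stratum := cut(x, breaks = qs, include.lowest = TRUE, right = TRUE,
                       labels = paste0("Q", seq_len(length(qs) - 1)))]
  }
  empty <- setdiff(levels(p$stratum), unique(as.character(p$stratum)))
  if (length(empty)) warning("empty strata omitted: ", paste(empty, collapse = ", "))

  res <- p[, agreement_row(.SD, config$agreement$weights,
                           config$agreement$conf_level), by = stratum]
  setorder(res, stratum)
  dist <- p[, {
    tab_l <- tabulate(local_stage + 1L, 4L)
    tab_c <- tabulate(central_stage + 1L, 4L)
    data.table(stage = 0:3,
               local_pct = 100 * tab_l / sum(tab_l),
               central_pct = 100 * tab_c / sum(tab_c))
  }, by = stratum]
  setorder(dist, stratum, stage)
  list(results = res[], stage_distribution = dist[], cutpoints = qs)
}

#' Cohort and alert descriptives
#'
#' The descriptive surface of a validation run: person counts, age and sex,
#' nonzero alert counts and stage mix for both raters, per-stage creatinine
#' at alert, reference-value medians, alerts per person, and result volumes
#' before the first / after the last alert.
#'
#' @param x `aki_cohort`
#' @param pairs from [build_pairs()]
#' @param central engine output
#' @return `data.table` with `metric` and `value` columns (class
#'   `aki_table1`)
#' @export
build_table1 <- function(x, pairs, central) {
  res <- x$results
  al <- x$alerts
  cen <- as.data.table(central)
  row <- function(metric, value) data.table(metric = metric, value = as.numeric(value))
  iqr3 <- function(v, name) {
    q <- quantile(v, c(0.5, 0.25, 0.75), na.rm = TRUE, names = FALSE, type = 7)
    rbindlist(list(row(paste0(name, "_median"), q[1]),
                   row(paste0(name, "_q1"), q[2]),
                   row(paste0(name, "_q3"), q[3])))
  }

  first_age <- res[, .(age = whole_years(dob[1L], min(specimen_dt))), by = mpi]
  sex_tab <- res[, .(sex = sex[1L]), by = mpi]
  cen_nz <- cen[stage >= 1L]

  out <- list(
    row("n_persons", uniqueN(res$mpi)),
    row("n_results", nrow(res)),
    iqr3(first_age$age, "age"),
    row("pct_female", 100 * mean(sex_tab$sex == "F")),
    row("local_alerts_total", nrow(al)),
    row("central_alerts_total", nrow(cen_nz))
  )
  for (s in 1:3) {
    nl <- sum(al$stage == s)
    nc <- sum(cen_nz$stage == s)
    out <- c(out, list(
      row(sprintf("local_stage%d_n", s), nl),
      row(sprintf("local_stage%d_pct", s), if (nrow(al)) 100 * nl / nrow(al) else NA),
      row(sprintf("central_stage%d_n", s), nc),
      row(sprintf("central_stage%d_pct", s), if (nrow(cen_nz)) 100 * nc / nrow(cen_nz) else NA)),
      if (nl) list(iqr3(al[stage == s, scr_at_alert], sprintf("local_stage%d_scr", s))),
      if (nc) list(iqr3(cen_nz[stage == s, c1], sprintf("central_stage%d_scr", s))))
  }
  if (nrow(al)) {
    app <- al[, .N, by = mpi]$N
    out <- c(out, list(iqr3(app, "local_alerts_per_person"),
                       row("local_alerts_per_person_max", max(app))))
  }
  if (nrow(cen_nz)) {
    app_c <- cen_nz[, .N, by = mpi]$N
    out <- c(out, list(iqr3(app_c, "central_alerts_per_person"),
                       row("central_alerts_per_person_max", max(app_c))))
    out <- c(out, list(row("rv1_median", median(cen_nz$rv1, na.rm = TRUE)),
                       row("rv2_median", median(cen_nz$rv2, na.rm = TRUE))))
  }
  if (nrow(al)) {
    bounds <- al[, .(first_alert = min(alert_dt), last_alert = max(alert_dt)), by = mpi]
    rb <- bounds[res, on = "mpi", nomatch = NULL]
    out <- c(out, list(
      row("n_results_before_first_alert", rb[specimen_dt < first_alert, .N]),
      row("n_results_after_last_alert", rb[specimen_dt > last_alert, .N])))
  }
  t1 <- rbindlist(Filter(Negate(is.null), out))
  setattr(t1, "class", c("aki_table1", class(t1)))
  t1
}

#' Run the full validation study
#'
#' Orchestrates the pipeline: load or simulate a cohort, apply the cohort
#' exclusions (age window, post-KRT alert censoring), run the central
#' engine, pair local and central stages, and compute every analysis
#' surface — pooled matrix and coefficient, per-laboratory / per-LIMS /
#' per-year agreement, the complete-case and complete-months sensitivity
#' analyses, and baseline-creatinine and age subgroups. With
#' `config$output` set, a report bundle is written (`table1.csv`,
#' `table2.csv`, `table3.csv`, `lims.csv`, `years.csv`, `sensitivity.csv`,
#' `subgroups_scr.csv`, `subgroups_age.csv`, `run.json`); given the same
#' seed the bundle is byte-identical across runs.
#'
#' The configuration list (or YAML file) supplies exactly one input mode:
#' \describe{
#'   \item{`simulate`}{`list(params = ..., behavior = ...)` passed to
#'     [cohort_params()] and [lab_behavior()]; `config$seed` seeds the run.}
#'   \item{`input`}{`list(scr = , alerts = , krt = , lims = )` file paths
#'     for [read_submission()].}
#'   \item{`matrix`}{a 4x4 counts matrix (or CSV path): agreement-only mode
#'     computing the pooled and complete-case coefficients straight from a
#'     published-style cross-tabulation.}
#' }
#'
#' @param config nested list or YAML path; `engine`/`io`/`agreement` blocks
#'   override [akival_config()] defaults
#' @return `aki_study_report` list
#' @export
run_study <- function(config = list()) {
  if (is.character(config)) config <- read_config(config, verbose = isTRUE(config$verbose))
  cfg <- akival_config(engine = config$engine %||% list(),
                       io = config$io %||% list(),
                       agreement = config$agreement %||% list())
  seed <- config$seed %||% 1L
  set.seed(seed)
  verbose <- isTRUE(config$verbose)
  say <- function(...) if (verbose) message(sprintf(...))

  # ---- matrix-only mode -------------------------------------------------
  if (!is.null(config$matrix)) {
    m <- config$matrix
    if (is.character(m)) m <- as.matrix(fread(m, header = FALSE))
    m <- as_confusion(unname(as.matrix(m)))
    overall <- gwet_ac1(m, weights = cfg$agreement$weights,
                        conf_level = cfg$agreement$conf_level)
    mcc <- unclass(m)
    mcc[1, ] <- 0L  # discard inferred local zeros, keep q = 4
    cc <- gwet_ac1(as_confusion(mcc), weights = cfg$agreement$weights,
                   conf_level = cfg$agreement$conf_level)
    report <- structure(list(mode = "matrix", seed = seed, config = cfg,
                             table2 = m, overall = overall,
                             sensitivity = list(complete_case = cc)),
                        class = "aki_study_report")
    if (!is.null(config$output)) write_report(report, config$output)
    return(report)
  }

  # ---- cohort modes -----------------------------------------------------
  truth <- NULL
  if (!is.null(config$input)) {
    inp <- config$input
    co <- read_submission(inp$scr, inp$alerts, cfg,
                          krt_path = inp$krt, lims_path = inp$lims)
    say("read: %d results, %d alerts", nrow(co$results), nrow(co$alerts))
  } else {
    simc <- config$simulate %||% list()
    params <- do.call(cohort_params, c(simc$params %||% list(), list(seed = NULL)))
    behavior <- if (inherits(simc$behavior, "lab_behavior") || is.list(simc$behavior) &&
                    !is.null(names(simc$behavior)) && all(vapply(simc$behavior, inherits, TRUE, "lab_behavior"))) {
      simc$behavior
    } else {
      do.call(lab_behavior, simc$behavior %||% list())
    }
    sim <- simulate_registry(params, behavior, cfg)
    co <- sim$cohort
    truth <- sim$truth
    say("simulated: %d results, %d alerts", nrow(co$results), nrow(co$alerts))
  }
  if (nrow(co$results) == 0) stop("empty cohort: nothing to analyse")

  n0 <- nrow(co$results)
  co <- apply_age_exclusion(co, cfg)
  say("age exclusion: %d -> %d results", n0, nrow(co$results))
  co <- censor_post_krt(co, cfg)
  say("post-KRT censoring: %d alerts removed",
      co$report$krt$alerts_censored %||% 0L)

  completeness <- assess_monthly_completeness(co)
  central <- run_central_algorithm(co, cfg)
  live <- determine_live_dates(co$alerts)
  pairs <- build_pairs(co, central, live, cfg)
  say("pairs: %d evaluable of %d results", nrow(pairs), nrow(co$results))
  if (nrow(pairs) == 0) stop("no evaluable pairs (no laboratory has a live date?)")

  overall <- overall_analysis(pairs, cfg)
  table3 <- per_group_analysis(pairs, "lab", config = cfg)
  lims_tab <- per_group_analysis(pairs, "lims", lims_map = co$lims_map, config = cfg)
  years <- per_group_analysis(pairs, "year", config = cfg)
  cc <- tryCatch(sensitivity_complete_case(pairs, cfg), error = function(e) NULL)
  cmo <- tryCatch(sensitivity_complete_months(pairs, completeness, cfg),
                  error = function(e) NULL)
  sub_scr <- subgroup_analysis(pairs, "baseline_scr", config = cfg)
  sub_age <- subgroup_analysis(pairs, "age", config = cfg)
  table1 <- build_table1(co, pairs, central)

  report <- structure(list(
    mode = if (!is.null(config$input)) "input" else "simulate",
    seed = seed, config = cfg,
    cohort_report = co$report,
    table1 = table1, table2 = overall$matrix, overall = overall$agreement,
    table3 = table3, lims = lims_tab, years = years,
    sensitivity = list(complete_case = cc, complete_months = cmo),
    subgroups = list(baseline_scr = sub_scr, age = sub_age),
    completeness = completeness, live_dates = live,
    n_pairs = nrow(pairs), truth = truth
  ), class = "aki_study_report")
  if (!is.null(config$output)) write_report(report, config$output)
  report
}

#' @export
print.aki_study_report <- function(x, ...) {
  cat(sprintf("<aki_study_report> mode=%s seed=%s\n", x$mode, x$seed))
  cat(sprintf("  overall coefficient: %.4f (%s)\n",
              x$overall$coefficient, x$overall$band))
  if (!is.null(x$sensitivity$complete_case)) {
    cat(sprintf("  complete-case:       %.4f\n",
                x$sensitivity$complete_case$coefficient))
  }
  if (!is.null(x$table3)) {
    cat(sprintf("  per-lab coefficients: %s\n",
                paste(sprintf("%.3f", x$table3$coefficient), collapse = " ")))
  }
  invisible(x)
}

agreement_json <- function(ag) {
  if (is.null(ag)) return(NULL)
  list(coefficient = round(ag$coefficient, 4), pa = round(ag$pa, 4),
       pa_unweighted = round(ag$pa_unweighted, 4), pe = round(ag$pe, 4),
       se = signif(ag$se, 4), ci = round(ag$ci, 4), n = ag$n,
       band = ag$band, acceptable = ag$acceptable)
}

round_cols <- function(dt, digits = 4) {
  dt <- copy(dt)
  num <- names(dt)[vapply(dt, is.double, TRUE)]
  for (cn in num) set(dt, j = cn, value = round_half_up(dt[[cn]], digits))
  dt
}

#' Write a study report bundle
#'
#' @param report `aki_study_report`
#' @param dir output directory (created if needed)
#' @return invisibly, the directory
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "aki_study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- unclass(report$table2)
  fwrite(as.data.table(m, keep.rownames = "local_stage"),
         file.path(dir, "table2.csv"), quote = FALSE)
  run <- list(mode = report$mode, seed = report$seed,
              package_version = as.character(utils::packageVersion("akival")),
              config = unclass(report$config),
              n_pairs = report$n_pairs,
              overall = agreement_json(report$overall),
              sensitivity = list(
                complete_case = agreement_json(report$sensitivity$complete_case),
                complete_months = agreement_json(report$sensitivity$complete_months$agreement)))
  jsonlite::write_json(run, file.path(dir, "run.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  if (report$mode == "matrix") return(invisible(dir))

  fwrite(round_cols(report$table1), file.path(dir, "table1.csv"), quote = FALSE)
  fwrite(round_cols(report$table3), file.path(dir, "table3.csv"), quote = FALSE)
  fwrite(round_cols(report$lims), file.path(dir, "lims.csv"), quote = FALSE)
  fwrite(round_cols(report$years), file.path(dir, "years.csv"), quote = FALSE)

  sens <- rbindlist(list(
    if (!is.null(report$sensitivity$complete_case))
      data.table(analysis = "complete_case",
                 coefficient = report$sensitivity$complete_case$coefficient,
                 n = report$sensitivity$complete_case$n),
    if (!is.null(report$sensitivity$complete_months))
      data.table(analysis = "complete_months",
                 coefficient = report$sensitivity$complete_months$agreement$coefficient,
                 n = report$sensitivity$complete_months$agreement$n)
  ))
  if (nrow(sens)) fwrite(round_cols(sens), file.path(dir, "sensitivity.csv"), quote = FALSE)
  fwrite(round_cols(report$subgroups$baseline_scr$results),
         file.path(dir, "subgroups_scr.csv"), quote = FALSE)
  fwrite(round_cols(report$subgroups$age$results),
         file.path(dir, "subgroups_age.csv"), quote = FALSE)
  invisible(dir)
}
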