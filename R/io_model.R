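# Submission-file model: domain types, readers/writers, validation,
# deduplication and cohort exclusions.

SCR_COLS <- c("mpi", "lab_code", "specimen_dt", "scr_umol_l", "dob", "sex",
              "location_code")
ALERT_COLS <- c("mpi", "lab_code", "alert_dt", "stage", "scr_at_alert")

#' Construct a cohort from in-memory tables
#'
#' A cohort bundles the two registry streams — serum-creatinine results and
#' laboratory AKI alerts — together with the optional
#' kidney-replacement-therapy start dates and the laboratory-to-LIMS-provider
#' map. Rows are canonicalised (types coerced, timestamps truncated to the
#' minute, ordered by patient then time) but not validated or deduplicated;
#' use [read_submission()] for full validation of external files.
#'
#' @param results data.frame with columns `mpi`, `lab_code`, `specimen_dt`,
#'   `scr` (umol/L), `dob`, `sex`, and optionally `location_code`
#' @param alerts data.frame with columns `mpi`, `lab_code`, `alert_dt`,
#'   `stage` (1--3), and optionally `scr_at_alert`; may have zero rows
#' @param krt_start optional data.frame `mpi`, `krt_start_date`
#' @param lims_map optional data.frame `lab_code`, `lims_provider`
#' @param report optional named list of read/rejection counters
#' @return object of class `aki_cohort`
#' @export
cohort <- function(results, alerts = NULL, krt_start = NULL, lims_map = NULL,
                   report = list()) {
  res <- as.data.table(results)
  need <- c("mpi", "lab_code", "specimen_dt", "scr", "dob", "sex")
  miss <- setdiff(need, names(res))
  if (length(miss)) stop("results missing columns: ", paste(miss, collapse = ", "))
  if (!"location_code" %in% names(res)) res[, location_code := NA_character_]
  res[, `:=`(mpi = as.character(mpi), lab_code = as.character(lab_code),
             scr = as.numeric(scr), dob = as.Date(dob),
             sex = norm_sex(sex), location_code = as.character(location_code))]
  if (!inherits(res$specimen_dt, "POSIXct")) res[, specimen_dt := parse_dt(specimen_dt)]
  res[, specimen_dt := trunc_minute(specimen_dt)]
  setorder(res, mpi, specimen_dt, scr, na.last = TRUE)

  if (is.null(alerts) || nrow(as.data.table(alerts)) == 0) {
    al <- empty_alerts()
  } else {
    al <- as.data.table(alerts)
    miss <- setdiff(c("mpi", "lab_code", "alert_dt", "stage"), names(al))
    if (length(miss)) stop("alerts missing columns: ", paste(miss, collapse = ", "))
    if (!"scr_at_alert" %in% names(al)) al[, scr_at_alert := NA_real_]
    al[, `:=`(mpi = as.character(mpi), lab_code = as.character(lab_code),
              stage = as.integer(stage), scr_at_alert = as.numeric(scr_at_alert))]
    if (!inherits(al$alert_dt, "POSIXct")) al[, alert_dt := parse_dt(alert_dt)]
    al[, alert_dt := trunc_minute(alert_dt)]
    if (any(!al$stage %in% 1:3)) stop("alert stages must be in 1..3")
    setorder(al, mpi, alert_dt, stage)
  }

  if (!is.null(krt_start)) {
    krt_start <- as.data.table(krt_start)
    krt_start[, `:=`(mpi = as.character(mpi), krt_start_date = as.Date(krt_start_date))]
  }
  if (!is.null(lims_map)) {
    lims_map <- as.data.table(lims_map)
    lims_map[, `:=`(lab_code = as.character(lab_code),
                    lims_provider = as.character(lims_provider))]
  }
  structure(list(results = res, alerts = al, krt_start = krt_start,
                 lims_map = lims_map, report = report),
            class = "aki_cohort")
}

empty_alerts <- function() {
  data.table(mpi = character(), lab_code = character(),
             alert_dt = as.POSIXct(character(), tz = "UTC"),
             stage = integer(), scr_at_alert = numeric())
}

norm_sex <- function(x) {
  x <- toupper(substr(trimws(as.character(x)), 1, 1))
  out <- rep("unknown", length(x))
  out[x == "F"] <- "F"
  out[x == "M"] <- "M"
  out
}

#' @export
print.aki_cohort <- function(x, ...) {
  cat("<aki_cohort>\n")
  cat(sprintf("  results: %d rows, %d patients, %d labs\n",
              nrow(x$results), uniqueN(x$results$mpi), uniqueN(x$results$lab_code)))
  cat(sprintf("  alerts:  %d rows (stages: %s)\n", nrow(x$alerts),
              paste(sprintf("%d=%d", 1:3, tabulate(x$alerts$stage, 3)), collapse = " ")))
  if (!is.null(x$krt_start)) cat(sprintf("  krt_start: %d patients\n", nrow(x$krt_start)))
  if (!is.null(x$lims_map)) cat(sprintf("  lims_map:  %d labs\n", nrow(x$lims_map)))
  if (length(x$report)) cat("  read report attached\n")
  invisible(x)
}

#' Read and validate a registry submission
#'
#' Parses the creatinine and alert CSV files (UTF-8, comma-separated, header
#' mandatory, ISO-8601 date-times), rejecting rows that fail validation and
#' counting them by reason. A malformed header is fatal; individual bad rows
#' are logged, not fatal, unless the overall reject rate exceeds
#' `config$io$reject_threshold` (default 5%).
#'
#' Validation and deduplication rules:
#' * creatinine must be a positive number below `config$io$scr_max`
#'   (physiologic plausibility, default 4000 umol/L) — reason `bad_scr`;
#' * date-times must parse — `bad_datetime`; a specimen dated before the
#'   recorded birth date is rejected — `dt_before_dob`;
#' * alert stages outside `{1,2,3}` are rejected — `bad_stage` (the registry
#'   never receives stage-0 alerts; zeros are inferred downstream);
#' * duplicate = identical `(mpi, specimen_dt, scr)`; extra copies are
#'   dropped — `duplicates`. Rows sharing `(mpi, specimen_dt)` but differing
#'   in value are both kept and counted as `same_time_conflicts`.
#'
#' @param scr_path creatinine CSV: columns
#'   `mpi,lab_code,specimen_dt,scr_umol_l,dob,sex,location_code`
#' @param alert_path alert CSV: columns
#'   `mpi,lab_code,alert_dt,stage,scr_at_alert`
#' @param config [akival_config()] list
#' @param krt_path optional CSV `mpi,krt_start_date`
#' @param lims_path optional CSV `lab_code,lims_provider`
#' @return validated, deduplicated `aki_cohort`; `$report` holds per-stream
#'   counters (`read`, `kept`, and one entry per rejection reason)
#' @export
read_submission <- function(scr_path, alert_path, config = akival_config(),
                            krt_path = NULL, lims_path = NULL) {
  scr_raw <- fread(scr_path, colClasses = "character", na.strings = c("", "NA"))
  if (!all(SCR_COLS[1:6] %in% names(scr_raw))) {
    stop("malformed SCr header: need columns ", paste(SCR_COLS[1:6], collapse = ","))
  }
  if (!"location_code" %in% names(scr_raw)) scr_raw[, location_code := NA_character_]
  al_raw <- fread(alert_path, colClasses = "character", na.strings = c("", "NA"))
  if (!all(ALERT_COLS[1:4] %in% names(al_raw))) {
    stop("malformed alert header: need columns ", paste(ALERT_COLS[1:4], collapse = ","))
  }
  if (!"scr_at_alert" %in% names(al_raw)) al_raw[, scr_at_alert := NA_character_]

  # --- creatinine stream ------------------------------------------------
  n0 <- nrow(scr_raw)
  scr_raw[, `:=`(scr = suppressWarnings(as.numeric(scr_umol_l)),
                 specimen_dt = parse_dt(specimen_dt),
                 dob = suppressWarnings(as.Date(dob)))]
  bad_scr <- is.na(scr_raw$scr) | scr_raw$scr <= 0 | scr_raw$scr >= config$io$scr_max
  bad_dt <- !bad_scr & is.na(scr_raw$specimen_dt)
  bad_dob <- !bad_scr & !bad_dt & !is.na(scr_raw$dob) &
    as.Date(scr_raw$specimen_dt) < scr_raw$dob
  res <- scr_raw[!(bad_scr | bad_dt | bad_dob)]
  dup <- duplicated(res, by = c("mpi", "specimen_dt", "scr"))
  res <- res[!dup]
  conflicts <- res[, .N, by = .(mpi, specimen_dt)][N > 1L, sum(N - 1L)]
  if (length(conflicts) == 0) conflicts <- 0L
  scr_report <- list(read = n0, kept = nrow(res),
                     bad_scr = sum(bad_scr), bad_datetime = sum(bad_dt),
                     dt_before_dob = sum(bad_dob), duplicates = sum(dup),
                     same_time_conflicts = conflicts)

  # --- alert stream -----------------------------------------------------
  m0 <- nrow(al_raw)
  al_raw[, `:=`(stage_i = suppressWarnings(as.integer(stage)),
                alert_dt = parse_dt(alert_dt),
                scr_at_alert = suppressWarnings(as.numeric(scr_at_alert)))]
  bad_stage <- is.na(al_raw$stage_i) | !al_raw$stage_i %in% 1:3
  bad_adt <- !bad_stage & is.na(al_raw$alert_dt)
  al <- al_raw[!(bad_stage | bad_adt)]
  al[, stage := stage_i]
  dup_a <- duplicated(al, by = c("mpi", "lab_code", "alert_dt", "stage"))
  al <- al[!dup_a]
  alert_report <- list(read = m0, kept = nrow(al),
                       bad_stage = sum(bad_stage), bad_datetime = sum(bad_adt),
                       duplicates = sum(dup_a))

  rej_rate <- (sum(bad_scr) + sum(bad_dt) + sum(bad_dob) + sum(bad_stage) + sum(bad_adt)) /
    max(1L, n0 + m0)
  if (rej_rate > config$io$reject_threshold) {
    stop(sprintf("reject rate %.1f%% exceeds threshold %.1f%%",
                 100 * rej_rate, 100 * config$io$reject_threshold))
  }

  krt <- if (!is.null(krt_path)) fread(krt_path, colClasses = "character") else NULL
  lims <- if (!is.null(lims_path)) fread(lims_path, colClasses = "character") else NULL

  cohort(results = res[, .(mpi, lab_code, specimen_dt, scr, dob, sex, location_code)],
         alerts = if (nrow(al)) al[, .(mpi, lab_code, alert_dt, stage, scr_at_alert)] else NULL,
         krt_start = krt, lims_map = lims,
         report = list(scr = scr_report, alerts = alert_report))
}

#' Write a cohort back to submission CSV files
#'
#' Emits the same dialect [read_submission()] consumes, in canonical order,
#' so that write -> read -> write is byte-stable.
#'
#' @param x `aki_cohort`
#' @param scr_path,alert_path output paths
#' @return invisibly, the two paths
#' @export
write_submission <- function(x, scr_path, alert_path) {
  stopifnot(inherits(x, "aki_cohort"))
  res <- x$results[, .(mpi, lab_code, specimen_dt = format_dt(specimen_dt),
                       scr_umol_l = fmt_num(scr), dob = format(dob), sex,
                       location_code)]
  fwrite(res, scr_path, na = "", quote = FALSE)
  al <- x$alerts[, .(mpi, lab_code, alert_dt = format_dt(alert_dt), stage,
                     scr_at_alert = fmt_num(scr_at_alert))]
  fwrite(al, alert_path, na = "", quote = FALSE)
  invisible(c(scr_path, alert_path))
}

fmt_num <- function(x) {
  out <- formatC(x, format = "fg", digits = 15)
  out[is.na(x)] <- NA_character_
  trimws(out)
}

#' Exclude results outside the adult age window
#'
#' Retains creatinine results (and alerts) only for tests taken at a
#' completed age between `config$io$age_min` and `config$io$age_max` years
#' inclusive (defaults 18 and 99; outside this window the recorded birth
#' date is considered unreliable). Age is evaluated at each record's own
#' date; alerts use the patient's birth date carried on their creatinine
#' rows. Records with no usable birth date are excluded with reason
#' `missing_dob`.
#'
#' @param x `aki_cohort`
#' @param config [akival_config()]
#' @return filtered `aki_cohort`; `$report$age` holds exclusion counts
#' @export
apply_age_exclusion <- function(x, config = akival_config()) {
  stopifnot(inherits(x, "aki_cohort"))
  res <- copy(x$results)
  lo <- config$io$age_min
  hi <- config$io$age_max
  age <- whole_years(res$dob, res$specimen_dt)
  missing_dob <- is.na(age)
  keep_res <- !missing_dob & age >= lo & age <= hi

  dob_map <- res[!is.na(dob), .(dob = dob[1L]), by = mpi]
  al <- copy(x$alerts)
  if (nrow(al)) {
    al <- dob_map[al, on = "mpi"]
    age_a <- whole_years(al$dob, al$alert_dt)
    miss_a <- is.na(age_a)
    keep_al <- !miss_a & age_a >= lo & age_a <= hi
  } else {
    keep_al <- logical(0)
    miss_a <- logical(0)
  }

  rep <- x$report
  rep$age <- list(results_excluded = sum(!keep_res),
                  alerts_excluded = sum(!keep_al),
                  missing_dob = sum(missing_dob) + sum(miss_a))
  cohort(results = res[keep_res],
         alerts = if (any(keep_al)) al[keep_al, .(mpi, lab_code, alert_dt, stage, scr_at_alert)] else NULL,
         krt_start = x$krt_start, lims_map = x$lims_map, report = rep)
}

#' Censor alerts after the start of kidney replacement therapy
#'
#' Patients who start long-term dialysis stop being eligible for AKI
#' alerting; alerts dated on or after the recorded start date are removed to
#' avoid pre-/post-dialysis alerts. Creatinine results are retained by
#' default — they remain legitimate look-back history — unless
#' `config$io$krt_drop_scr` is `TRUE`.
#'
#' @param x `aki_cohort` (with `$krt_start`, possibly empty, or `NULL` for
#'   a no-op)
#' @param config [akival_config()]
#' @return censored `aki_cohort`; `$report$krt$alerts_censored` counts
#'   removals
#' @export
censor_post_krt <- function(x, config = akival_config()) {
  stopifnot(inherits(x, "aki_cohort"))
  if (is.null(x$krt_start) || nrow(x$krt_start) == 0) return(x)
  al <- copy(x$alerts)
  res <- copy(x$results)
  n_al <- 0L
  n_res <- 0L
  if (nrow(al)) {
    al <- x$krt_start[al, on = "mpi"]
    drop <- !is.na(al$krt_start_date) & as.Date(al$alert_dt) >= al$krt_start_date
    n_al <- sum(drop)
    al <- al[!drop, .(mpi, lab_code, alert_dt, stage, scr_at_alert)]
  }
  if (isTRUE(config$io$krt_drop_scr) && nrow(res)) {
    res <- x$krt_start[res, on = "mpi"]
    drop_r <- !is.na(res$krt_start_date) & as.Date(res$specimen_dt) >= res$krt_start_date
    n_res <- sum(drop_r)
    res <- res[!drop_r, .(mpi, lab_code, specimen_dt, scr, dob, sex, location_code)]
  }
  rep <- x$report
  rep$krt <- list(alerts_censored = n_al, results_censored = n_res)
  cohort(results = res, alerts = if (nrow(al)) al else NULL,
         krt_start = x$krt_start, lims_map = x$lims_map, report = rep)
}

#' Per-month submission completeness flags
#'
#' For each calendar month between a laboratory's first and last submitted
#' record (either stream), reports whether the month contains any creatinine
#' rows and any alert rows. A laboratory is designated *complete* only if
#' every month in its span has both.
#'
#' @param x `aki_cohort`
#' @param lab optional single laboratory code; default all labs
#' @return `data.table` with columns `lab_code`, `month` ("YYYY-MM"),
#'   `has_scr`, `has_alerts`
#' @seealso [lab_completeness()]
#' @export
assess_monthly_completeness <- function(x, lab = NULL) {
  stopifnot(inherits(x, "aki_cohort"))
  res_m <- x$results[, .(lab_code, month = month_key(specimen_dt))]
  al_m <- x$alerts[, .(lab_code, month = month_key(alert_dt))]
  labs <- sort(unique(c(res_m$lab_code, al_m$lab_code)))
  if (!is.null(lab)) labs <- intersect(labs, lab)
  out <- rbindlist(lapply(labs, function(l) {
    mo <- c(res_m[lab_code == l, month], al_m[lab_code == l, month])
    span <- seq(as.Date(paste0(min(mo), "-01")), as.Date(paste0(max(mo), "-01")),
                by = "month")
    keys <- format(span, "%Y-%m")
    data.table(lab_code = l, month = keys,
               has_scr = keys %in% res_m[lab_code == l, month],
               has_alerts = keys %in% al_m[lab_code == l, month])
  }))
  out[]
}

#' Laboratory-level completeness summary
#'
#' @param x `aki_cohort` or the flag table from
#'   [assess_monthly_completeness()]
#' @return `data.table` with `lab_code` and logical `complete`
#' @export
lab_completeness <- function(x) {
  flags <- if (inherits(x, "aki_cohort")) assess_monthly_completeness(x) else as.data.table(x)
  flags[, .(complete = all(has_scr & has_alerts)), by = lab_code][]
}
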