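# Central re-implementation of the NHS England AKI detection algorithm:
# reference-value windows over each patient's longitudinal creatinine
# series, KDIGO-style staging with the extended 365-day look-back,
# laboratory live dates, and local stage inference.

#' Reference values for one index result
#'
#' Given one patient's creatinine series (at a single laboratory) sorted by
#' time, computes the three comparators the detection algorithm uses for the
#' result at position `index`:
#' \describe{
#'   \item{rv1}{lowest creatinine with a specimen time in the open interval
#'     (t - 7 days, t);}
#'   \item{rv2}{median creatinine over [t - 365 days, t - 7 days] — a result
#'     exactly 7 days old belongs to RV2, not RV1, so the two windows
#'     partition the look-back; an even count takes the mean of the two
#'     middle values;}
#'   \item{min_48h}{lowest creatinine in (t - 48 h, t), the comparator for
#'     the absolute-rise rule.}
#' }
#' The index result itself (and any result sharing its exact timestamp) is
#' excluded from all windows. Windows with no result yield `NA`.
#'
#' @param times POSIXct (or numeric seconds) specimen times, sorted ascending
#' @param values creatinine results, umol/L, same length
#' @param index position of the index result in the series
#' @param config [akival_config()]
#' @return list with `rv1`, `rv2`, `min_48h` (each a scalar or `NA`)
#' @export
#' @examples
#' t0 <- as.POSIXct("2019-06-01 08:00", tz = "UTC")
#' compute_reference_values(t0 + c(-5, -2, 0) * 86400, c(60, 80, 90), 3)
compute_reference_values <- function(times, values, index,
                                     config = akival_config()) {
  stopifnot(length(times) == length(values), index >= 1, index <= length(values))
  tn <- as.numeric(times)
  stopifnot(!is.unsorted(tn))
  rv <- .reference_values(tn, values, config$engine)
  list(rv1 = rv$rv1[index], rv2 = rv$rv2[index], min_48h = rv$min_48h[index])
}

# window scan for a whole sorted series; O(m^2) but series are short
.reference_values <- function(tn, v, eng) {
  m <- length(tn)
  rv1 <- rv2 <- m48 <- rep(NA_real_, m)
  if (m < 2L) return(list(rv1 = rv1, rv2 = rv2, min_48h = m48))
  w1 <- eng$rv1_days * 86400
  w2 <- eng$rv2_days * 86400
  w48 <- eng$delta_hours * 3600
  for (i in 2:m) {
    d <- tn[i] - tn[1:(i - 1)]
    vi <- v[1:(i - 1)]
    in1 <- d > 0 & d < w1
    in2 <- d >= w1 & d <= w2
    in48 <- d > 0 & d < w48
    if (any(in1)) rv1[i] <- min(vi[in1])
    if (any(in2)) rv2[i] <- median(vi[in2])
    if (any(in48)) m48[i] <- min(vi[in48])
  }
  list(rv1 = rv1, rv2 = rv2, min_48h = m48)
}

#' Stage one index creatinine against its reference values
#'
#' Applies the creatinine-ratio and absolute-rise rules:
#' the staging ratio is the larger of C1/RV1 and C1/RV2 (or the RV1 ratio
#' alone under `ratio_mode = "prefer_rv1"`). Stage 3 fires at ratio >= 3, or
#' at ratio >= 1.5 with C1 >= 354 umol/L (the high-creatinine escalation,
#' config-gated); stage 2 at 2 <= ratio < 3; stage 1 at 1.5 <= ratio < 2,
#' or — when the ratio is below 1.5 or no reference value exists — when the
#' rise over the lowest result of the past 48 h exceeds 26 umol/L (strict).
#' Otherwise stage 0. The ratio boundaries at 1.5, 2 and 3 are inclusive.
#'
#' @param c1 index creatinine, umol/L (> 0); vectorised
#' @param rv list with `rv1`, `rv2`, `min_48h` as returned by
#'   [compute_reference_values()] (vectors recycled against `c1`)
#' @param config [akival_config()]
#' @return list with `stage` (integer 0--3), `ratio_rv1`, `ratio_rv2`, and
#'   `rule_fired` in `{"ratio","delta48","high_c1","none"}`
#' @export
#' @examples
#' stage_result(90, list(rv1 = 60, rv2 = NA, min_48h = NA))$stage   # 1
#' stage_result(180, list(rv1 = NA, rv2 = 60, min_48h = NA))$stage  # 3
stage_result <- function(c1, rv, config = akival_config()) {
  stopifnot(all(c1 > 0, na.rm = TRUE))
  n <- length(c1)
  rv1 <- rep_len(rv$rv1 %||% NA_real_, n)
  rv2 <- rep_len(rv$rv2 %||% NA_real_, n)
  m48 <- rep_len(rv$min_48h %||% NA_real_, n)
  eng <- config$engine

  r1 <- c1 / rv1
  r2 <- c1 / rv2
  ratio <- switch(eng$ratio_mode,
    both = pmax(fifelse(is.na(r1), -Inf, r1), fifelse(is.na(r2), -Inf, r2)),
    prefer_rv1 = fifelse(!is.na(r1), r1, fifelse(is.na(r2), -Inf, r2)),
    stop("unknown ratio_mode: ", eng$ratio_mode))
  # -Inf encodes "no reference value available"

  stage <- integer(n)
  rule <- rep("none", n)

  hit3 <- ratio >= eng$ratio_stage3
  stage[hit3] <- 3L
  rule[hit3] <- "ratio"

  if (isTRUE(eng$high_c1_enabled)) {
    hitH <- !hit3 & ratio >= eng$ratio_stage1 & c1 >= eng$high_c1_umol
    stage[hitH] <- 3L
    rule[hitH] <- "high_c1"
  } else hitH <- rep(FALSE, n)

  hit2 <- !hit3 & !hitH & ratio >= eng$ratio_stage2
  stage[hit2] <- 2L
  rule[hit2] <- "ratio"

  hit1 <- !hit3 & !hitH & !hit2 & ratio >= eng$ratio_stage1
  stage[hit1] <- 1L
  rule[hit1] <- "ratio"

  hitD <- ratio < eng$ratio_stage1 & !is.na(m48) & (c1 - m48 > eng$delta48_umol)
  stage[hitD] <- 1L
  rule[hitD] <- "delta48"

  list(stage = stage,
       ratio_rv1 = r1, ratio_rv2 = r2,
       rule_fired = rule)
}

#' Run the central algorithm over a whole cohort
#'
#' Recomputes an alert stage (possibly 0) for every creatinine result.
#' Each patient's series is processed chronologically within each
#' laboratory — a laboratory can only see its own results — and the output
#' is independent of the on-disk ordering of the input.
#'
#' @param x `aki_cohort`
#' @param config [akival_config()]
#' @param variant_configs optional named list, `lab_code` -> list of
#'   `engine` overrides, emulating laboratories running variant in-house
#'   rules
#' @return `data.table`, one row per result: `mpi`, `lab_code`,
#'   `specimen_dt`, `c1`, `rv1`, `rv2`, `min_48h`, `ratio_rv1`, `ratio_rv2`,
#'   `stage`, `rule_fired`
#' @export
run_central_algorithm <- function(x, config = akival_config(),
                                  variant_configs = NULL) {
  stopifnot(inherits(x, "aki_cohort"))
  res <- copy(x$results)
  setorder(res, mpi, specimen_dt, scr)
  labs <- unique(res$lab_code)
  cfg_for <- function(l) {
    ov <- variant_configs[[l]]
    if (is.null(ov)) config else merge_config(config, list(engine = ov))
  }
  same_cfg <- is.null(variant_configs)

  # look-back windows are evaluated within (patient, laboratory): a
  # laboratory's algorithm only sees the results it produced
  stage_lab <- function(dt, cfg) {
    dt <- copy(dt)
    dt[, c("rv1", "rv2", "min_48h") :=
         .reference_values(as.numeric(specimen_dt), scr, cfg$engine),
       by = .(mpi, lab_code)]
    st <- stage_result(dt$scr, list(rv1 = dt$rv1, rv2 = dt$rv2,
                                    min_48h = dt$min_48h), cfg)
    dt[, .(mpi, lab_code, specimen_dt, c1 = scr, rv1, rv2, min_48h,
           ratio_rv1 = st$ratio_rv1, ratio_rv2 = st$ratio_rv2,
           stage = st$stage, rule_fired = st$rule_fired)]
  }

  out <- if (same_cfg) {
    stage_lab(res, config)
  } else {
    rbindlist(lapply(labs, function(l) stage_lab(res[lab_code == l], cfg_for(l))))
  }
  setorder(out, mpi, specimen_dt, c1)
  out[]
}

#' Laboratory live dates
#'
#' The date of the first-ever alert received from a laboratory is taken as
#' the date its algorithm went live. Laboratories with no alerts have no
#' live date and contribute no inferred stage-0 records.
#'
#' @param alerts alert `data.table` (or an `aki_cohort`)
#' @return `data.table` with `lab_code`, `live_date` (Date)
#' @export
determine_live_dates <- function(alerts) {
  if (inherits(alerts, "aki_cohort")) alerts <- alerts$alerts
  al <- as.data.table(alerts)
  if (nrow(al) == 0) return(data.table(lab_code = character(), live_date = as.Date(character())))
  al[, .(live_date = as.Date(min(alert_dt))), by = lab_code][order(lab_code)]
}

#' Infer the local laboratory stage for each creatinine result
#'
#' Each received alert is linked to the nearest creatinine result from the
#' same patient and laboratory within the matching tolerance (default 24 h);
#' when two alerts land on one result the higher stage wins. Results with no
#' linked alert are recoded to stage 0 provided they are dated on or after
#' the laboratory's live date — before it, the local algorithm could not
#' have fired, so the result is not evaluable (`NA`).
#'
#' @param x `aki_cohort` (its alerts are used unless `alerts` is given)
#' @param live_dates from [determine_live_dates()]; computed if `NULL`
#' @param alerts optional alert table overriding `x$alerts`
#' @param config [akival_config()]
#' @return `data.table` aligned with `x$results` (canonical order): `mpi`,
#'   `lab_code`, `specimen_dt`, `local_stage` (integer or `NA`), `inferred`
#'   (TRUE where the 0 was inferred from alert absence)
#' @export
infer_local_stage <- function(x, live_dates = NULL, alerts = NULL,
                              config = akival_config()) {
  stopifnot(inherits(x, "aki_cohort"))
  al <- as.data.table(alerts %||% x$alerts)
  if (is.null(live_dates)) live_dates <- determine_live_dates(al)
  res <- copy(x$results)
  setorder(res, mpi, specimen_dt, scr)
  res[, rid := .I]
  tol <- config$engine$match_tolerance_hours * 3600

  matched <- data.table(rid = integer(), stage = integer())
  if (nrow(al) > 0 && nrow(res) > 0) {
    al <- copy(al)[, aid := .I]
    cand <- res[, .(rid, mpi, lab_code, specimen_dt)][
      al, on = c("mpi", "lab_code"), allow.cartesian = TRUE, nomatch = NULL]
    cand[, dt_diff := abs(as.numeric(specimen_dt) - as.numeric(alert_dt))]
    cand <- cand[dt_diff <= tol]
    if (nrow(cand)) {
      # each alert claims its nearest result (earlier result on a tie) ...
      setorder(cand, aid, dt_diff, rid)
      claimed <- cand[, .(rid = rid[1L], stage = stage[1L]), by = "aid"]
      # ... and a result keeps the highest stage among alerts it received
      matched <- claimed[, .(stage = max(stage)), by = rid]
    }
  }

  out <- merge(res[, .(rid, mpi, lab_code, specimen_dt)], matched,
               by = "rid", all.x = TRUE)
  out <- merge(out, live_dates, by = "lab_code", all.x = TRUE)
  out[, local_stage := stage]
  out[, inferred := FALSE]
  unmatched <- is.na(out$stage)
  evaluable <- unmatched & !is.na(out$live_date) &
    as.Date(out$specimen_dt) >= out$live_date
  out[evaluable, `:=`(local_stage = 0L, inferred = TRUE)]
  setorder(out, rid)
  out[, .(mpi, lab_code, specimen_dt, local_stage, inferred)]
}

#' Write central alerts to CSV
#'
#' @param central output of [run_central_algorithm()]
#' @param path output CSV
#' @return invisibly, the path
#' @export
write_central_alerts <- function(central, path) {
  out <- as.data.table(central)[, .(mpi, lab_code,
                                    specimen_dt = format_dt(specimen_dt),
                                    c1 = fmt_num(c1), stage,
                                    ratio_rv1 = fmt_num(round(ratio_rv1, 6)),
                                    ratio_rv2 = fmt_num(round(ratio_rv2, 6)),
                                    rule_fired)]
  fwrite(out, path, na = "", quote = FALSE)
  invisible(path)
}
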