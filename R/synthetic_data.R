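# Synthetic registry simulator: longitudinal creatinine trajectories with
# known ground truth, plus laboratory-behaviour corruption (stage
# miscoding, alert suppression, missing monthly files).

#' Parameters for the synthetic cohort generator
#'
#' Defaults emulate the marginal structure of a national AKI-alert registry
#' population: baseline creatinine log-normal with an overall median of
#' 77 umol/L and IQR roughly 57--108 (a mixture with a 15% elevated-baseline
#' CKD sub-population, median 164 umol/L); age with median ~72 years, IQR
#' ~60--82, truncated to the adult window 18--99; 47% female; AKI episode
#' severity mix 63/18/19% across stages 1/2/3.
#'
#' The non-CKD log-normal location is solved analytically so the *mixture*
#' median equals `baseline_median` for any `ckd_fraction`.
#'
#' @param n_patients number of patients (> 0)
#' @param months study duration in months
#' @param n_labs number of laboratories (patients are assigned to one lab)
#' @param start_date first day of the study window
#' @param baseline_median target overall baseline creatinine median, umol/L
#' @param baseline_sdlog log-scale SD of the non-CKD baseline distribution
#' @param ckd_fraction proportion of patients with elevated (CKD) baselines
#' @param ckd_median,ckd_sdlog CKD baseline log-normal parameters
#' @param age_median,age_sdlog age is `100 - LogNormal` (right-skewed toward
#'   old age), resampled into [18, 99]
#' @param frac_female proportion female
#' @param episode_rate AKI episodes per patient-year
#' @param stage_mix target severity proportions for stages 1/2/3 (sums to 1)
#' @param tests_per_month baseline (out-of-episode) testing intensity
#' @param episode_tests_per_day in-episode testing intensity
#' @param noise_cv coefficient of variation of multiplicative log-normal
#'   measurement noise
#' @param krt_fraction proportion of patients with a kidney-replacement-
#'   therapy start date inside the window
#' @param seed RNG seed; all randomness in a run flows from one global
#'   stream so a single seed reproduces the whole cohort
#' @return `cohort_params` list
#' @export
cohort_params <- function(n_patients = 500, months = 24, n_labs = 5,
                          start_date = as.Date("2018-01-01"),
                          baseline_median = 77, baseline_sdlog = 0.474,
                          ckd_fraction = 0.15, ckd_median = 164,
                          ckd_sdlog = 0.35,
                          age_median = 72.4, age_sdlog = 0.6,
                          frac_female = 0.47,
                          episode_rate = 0.8,
                          stage_mix = c(0.63, 0.18, 0.19),
                          tests_per_month = 1,
                          episode_tests_per_day = 0.5,
                          noise_cv = 0.05,
                          krt_fraction = 0.02,
                          seed = NULL) {
  stopifnot(n_patients >= 1, months >= 1, n_labs >= 1,
            length(stage_mix) == 3, all(stage_mix >= 0),
            abs(sum(stage_mix) - 1) < 1e-8,
            ckd_fraction >= 0, ckd_fraction <= 1,
            frac_female >= 0, frac_female <= 1,
            episode_rate >= 0, tests_per_month >= 0,
            episode_tests_per_day > 0, noise_cv >= 0)
  structure(as.list(environment()), class = "cohort_params")
}

# log-scale location of the non-CKD baseline component such that the
# CKD/non-CKD mixture has median `target`
.solve_baseline_meanlog <- function(target, sdlog, ckd_fraction, ckd_median,
                                    ckd_sdlog) {
  if (ckd_fraction >= 1) return(log(ckd_median))
  f2 <- plnorm(target, log(ckd_median), ckd_sdlog)
  p1 <- (0.5 - ckd_fraction * f2) / (1 - ckd_fraction)
  p1 <- min(max(p1, 1e-6), 1 - 1e-6)
  log(target) - sdlog * qnorm(p1)
}

#' Generate a synthetic registry cohort with ground truth
#'
#' Each patient receives a baseline creatinine (log-normal mixture), a
#' piecewise trajectory with Poisson-arriving AKI episodes — a
#' multiplicative rise to a stage-determined peak ratio over 1--5 days, then
#' exponential recovery over 3--21 days — multiplicative log-normal
#' measurement noise, and irregular specimen times: sparse baseline
#' sampling, dense in-episode sampling (with a draw at the episode peak, as
#' testing intensifies in the acutely unwell).
#'
#' The returned cohort carries *no alerts*: laboratory alerts, with their
#' corruption processes, come from [simulate_lab_alerts()].
#'
#' @param params [cohort_params()]
#' @return list of class `synthetic_cohort`: `cohort` (an `aki_cohort`),
#'   `patients` (per-patient truth: lab, sex, age, CKD flag, baseline) and
#'   `episodes` (per-episode truth: onset day, severity, peak ratio,
#'   rise/recovery durations)
#' @export
generate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  if (params$n_patients < 1) stop("n_patients must be positive")
  if (!is.null(params$seed)) set.seed(params$seed)
  p <- params
  n <- p$n_patients
  span_days <- p$months * 30.4375

  mpi <- sprintf("P%06d", seq_len(n))
  lab_code <- sprintf("L%02d", sample.int(p$n_labs, n, replace = TRUE))
  sex <- ifelse(runif(n) < p$frac_female, "F", "M")

  age <- 100 - stats::rlnorm(n, log(100 - p$age_median), p$age_sdlog)
  bad <- which(age < 18 | age > 99)
  while (length(bad)) {
    age[bad] <- 100 - stats::rlnorm(length(bad), log(100 - p$age_median), p$age_sdlog)
    bad <- which(age < 18 | age > 99)
  }
  dob <- p$start_date - round(age * 365.25)

  ckd <- runif(n) < p$ckd_fraction
  mu1 <- .solve_baseline_meanlog(p$baseline_median, p$baseline_sdlog,
                                 p$ckd_fraction, p$ckd_median, p$ckd_sdlog)
  baseline <- ifelse(ckd,
                     stats::rlnorm(n, log(p$ckd_median), p$ckd_sdlog),
                     stats::rlnorm(n, mu1, p$baseline_sdlog))

  krt <- runif(n) < p$krt_fraction
  krt_day <- ifelse(krt, runif(n, 0, span_days), NA_real_)

  sd_noise <- sqrt(log(1 + p$noise_cv^2))
  peak_lo <- c(1.55, 2.05, 3.10)
  peak_hi <- c(1.95, 2.90, 6.00)

  res_list <- vector("list", n)
  epi_list <- vector("list", n)
  for (i in seq_len(n)) {
    n_base <- rpois(1, p$tests_per_month * p$months)
    t_base <- runif(n_base, 0, span_days)

    n_epi <- rpois(1, p$episode_rate * p$months / 12)
    if (n_epi > 0) {
      e_start <- sort(runif(n_epi, 0, span_days))
      e_stage <- sample.int(3L, n_epi, replace = TRUE, prob = p$stage_mix)
      e_peak <- runif(n_epi, peak_lo[e_stage], peak_hi[e_stage])
      e_rise <- runif(n_epi, 1, 5)
      e_rec <- runif(n_epi, 3, 21)
      t_epi <- unlist(lapply(seq_len(n_epi), function(e) {
        grid <- seq(e_start[e], e_start[e] + e_rise[e] + e_rec[e],
                    by = 1 / p$episode_tests_per_day)
        c(grid + runif(length(grid), -0.3, 0.3), e_start[e] + e_rise[e])
      }))
      epi_list[[i]] <- data.table(mpi = mpi[i], onset_day = e_start,
                                  stage = e_stage, peak_ratio = e_peak,
                                  rise_days = e_rise, recovery_days = e_rec)
    } else {
      e_start <- e_peak <- e_rise <- e_rec <- numeric(0)
      t_epi <- numeric(0)
    }

    t_all <- sort(c(t_base, t_epi))
    t_all <- t_all[t_all >= 0 & t_all <= span_days]
    if (!length(t_all)) next

    fac <- rep(1, length(t_all))
    for (e in seq_along(e_start)) {
      dt <- t_all - e_start[e]
      rise <- dt >= 0 & dt <= e_rise[e]
      rec <- dt > e_rise[e]
      f <- rep(1, length(t_all))
      f[rise] <- 1 + (e_peak[e] - 1) * dt[rise] / e_rise[e]
      f[rec] <- 1 + (e_peak[e] - 1) * exp(-(dt[rec] - e_rise[e]) / (e_rec[e] / 3))
      fac <- pmax(fac, f)
    }
    scr_true <- baseline[i] * fac
    scr_obs <- scr_true * exp(rnorm(length(t_all), 0, sd_noise))
    scr_obs <- pmin(pmax(round(scr_obs, 1), 10), 3999)

    res_list[[i]] <- data.table(
      mpi = mpi[i], lab_code = lab_code[i],
      specimen_dt = trunc_minute(as.POSIXct(p$start_date, tz = "UTC") + t_all * 86400),
      scr = scr_obs, dob = dob[i], sex = sex[i],
      location_code = NA_character_)
  }

  res <- rbindlist(res_list)
  if (nrow(res) == 0) stop("generator produced no results; increase rates")
  # collapse accidental same-minute collisions (keep the first draw)
  res <- unique(res, by = c("mpi", "specimen_dt"))

  patients <- data.table(mpi = mpi, lab_code = lab_code, sex = sex,
                         dob = dob, age = age, ckd = ckd,
                         baseline_scr = baseline,
                         krt_day = krt_day)
  krt_tab <- patients[!is.na(krt_day),
                      .(mpi, krt_start_date = p$start_date + floor(krt_day))]
  labs <- sprintf("L%02d", seq_len(p$n_labs))
  providers <- sample(c("LIMS1", "LIMS2", "LIMS3", NA_character_),
                      p$n_labs, replace = TRUE, prob = c(0.2, 0.2, 0.2, 0.4))
  lims <- data.table(lab_code = labs, lims_provider = providers)[!is.na(lims_provider)]

  co <- cohort(results = res, alerts = NULL,
               krt_start = if (nrow(krt_tab)) krt_tab else NULL,
               lims_map = if (nrow(lims)) lims else NULL)
  structure(list(cohort = co, patients = patients,
                 episodes = rbindlist(epi_list), params = p),
            class = "synthetic_cohort")
}

#' Laboratory corruption model
#'
#' Describes how a simulated laboratory departs from faithful submission:
#' \describe{
#'   \item{suppression_prob}{probability that an issued alert is withheld;
#'     a scalar, or a length-3 vector for stages 1/2/3 (suppression of e.g.
#'     renal-unit or dialysis alerts is stage-targeted in practice).}
#'   \item{miscode_matrix}{4x4 row-stochastic matrix over stages 0--3; the
#'     submitted stage is drawn from the row of the true stage. Miscoding a
#'     nonzero stage to 0 means no alert is transmitted.}
#'   \item{monthly_missing_prob}{probability that an entire month's alert
#'     file is dropped for the laboratory.}
#'   \item{variant_config}{optional `engine` overrides (see
#'     [akival_config()]) emulating an in-house variant of the detection
#'     algorithm.}
#' }
#'
#' @param suppression_prob scalar or length-3 numeric in [0, 1]
#' @param miscode_matrix 4x4 row-stochastic matrix (default identity)
#' @param monthly_missing_prob numeric in [0, 1]
#' @param variant_config optional named list of engine overrides
#' @return `lab_behavior` list
#' @export
lab_behavior <- function(suppression_prob = 0, miscode_matrix = diag(4),
                         monthly_missing_prob = 0, variant_config = NULL) {
  if (length(suppression_prob) == 1) suppression_prob <- rep(suppression_prob, 3)
  stopifnot(length(suppression_prob) == 3,
            all(suppression_prob >= 0 & suppression_prob <= 1),
            all(dim(miscode_matrix) == c(4, 4)),
            all(miscode_matrix >= 0),
            all(abs(rowSums(miscode_matrix) - 1) < 1e-8),
            monthly_missing_prob >= 0, monthly_missing_prob <= 1)
  structure(list(suppression_prob = suppression_prob,
                 miscode_matrix = unname(as.matrix(miscode_matrix)),
                 monthly_missing_prob = monthly_missing_prob,
                 variant_config = variant_config),
            class = "lab_behavior")
}

#' Simulate laboratory alert submission with corruption
#'
#' Runs the central detection engine (honouring per-laboratory variant
#' engine configurations) to obtain the *true* alerts, then corrupts them in
#' a fixed order — miscode, then suppress, then drop whole months — and
#' emits only the surviving nonzero stages as alert records.
#'
#' Corruption draws are taken in a canonical order (patients then time) so
#' that, for a fixed seed, raising a suppression probability suppresses a
#' superset of alerts (common random numbers).
#'
#' @param x `aki_cohort` or `synthetic_cohort`
#' @param behavior a [lab_behavior()] applied to every laboratory, or a
#'   named list `lab_code -> lab_behavior` (unnamed labs get the default,
#'   faithful behaviour)
#' @param config [akival_config()]
#' @param central optional precomputed [run_central_algorithm()] output
#'   (only valid when no laboratory has a `variant_config`)
#' @param seed optional seed; by default draws continue the global stream
#' @return list: `alerts` (submission-ready alert `data.table`), `truth`
#'   (per true alert: true/submitted stage, suppression/miscoding/month-drop
#'   flags, `emitted`), `central` (the engine output used)
#' @export
simulate_lab_alerts <- function(x, behavior = lab_behavior(),
                                config = akival_config(), central = NULL,
                                seed = NULL) {
  co <- if (inherits(x, "synthetic_cohort")) x$cohort else x
  stopifnot(inherits(co, "aki_cohort"))
  if (!is.null(seed)) set.seed(seed)

  labs <- sort(unique(co$results$lab_code))
  beh_for <- function(l) {
    if (inherits(behavior, "lab_behavior")) return(behavior)
    behavior[[l]] %||% lab_behavior()
  }
  variants <- Filter(Negate(is.null),
                     setNames(lapply(labs, function(l) beh_for(l)$variant_config), labs))
  if (is.null(central)) {
    central <- run_central_algorithm(co, config,
                                     variant_configs = if (length(variants)) variants else NULL)
  } else if (length(variants)) {
    stop("cannot reuse precomputed central alerts with variant_config labs")
  }

  truth <- as.data.table(central)[stage >= 1L,
                                  .(mpi, lab_code, specimen_dt, c1, true_stage = stage)]
  setorder(truth, mpi, specimen_dt, c1)
  nt <- nrow(truth)

  # stage miscoding: inverse-CDF against one uniform per alert
  u_mis <- runif(nt)
  sub <- integer(nt)
  if (nt) {
    for (l in unique(truth$lab_code)) {
      mm <- beh_for(l)$miscode_matrix
      for (s in unique(truth$true_stage[truth$lab_code == l])) {
        idx <- which(truth$lab_code == l & truth$true_stage == s)
        brk <- c(0, cumsum(mm[s + 1L, ]))
        sub[idx] <- findInterval(u_mis[idx], brk, left.open = TRUE) - 1L
      }
    }
  }
  truth[, submitted_stage := sub]

  # suppression of submitted nonzero stages
  u_sup <- runif(nt)
  supp <- logical(nt)
  if (nt) {
    for (l in unique(truth$lab_code)) {
      sp <- beh_for(l)$suppression_prob
      idx <- which(truth$lab_code == l & truth$submitted_stage >= 1L)
      supp[idx] <- u_sup[idx] < sp[truth$submitted_stage[idx]]
    }
  }
  truth[, suppressed := supp]

  # whole-month file drops, over the cohort's calendar span per lab
  span <- range(as.Date(co$results$specimen_dt))
  mo_seq <- format(seq(as.Date(format(span[1], "%Y-%m-01")),
                       as.Date(format(span[2], "%Y-%m-01")), by = "month"), "%Y-%m")
  drop_tab <- rbindlist(lapply(labs, function(l) {
    u <- runif(length(mo_seq))
    data.table(lab_code = l, month = mo_seq,
               month_dropped = u < beh_for(l)$monthly_missing_prob)
  }))
  truth[, month := month_key(specimen_dt)]
  truth <- drop_tab[truth, on = c("lab_code", "month")]
  truth[is.na(month_dropped), month_dropped := FALSE]

  truth[, emitted := submitted_stage >= 1L & !suppressed & !month_dropped]
  setorder(truth, mpi, specimen_dt, c1)

  alerts <- truth[emitted == TRUE,
                  .(mpi, lab_code, alert_dt = specimen_dt,
                    stage = as.integer(submitted_stage), scr_at_alert = c1)]
  list(alerts = alerts,
       truth = truth[, .(mpi, lab_code, specimen_dt, c1, true_stage,
                         submitted_stage, suppressed, month_dropped, emitted)],
       central = central)
}

#' Generate a cohort and its (possibly corrupted) alert stream in one call
#'
#' @param params [cohort_params()] (its `seed` drives the whole run)
#' @param behavior see [simulate_lab_alerts()]
#' @param config [akival_config()]
#' @return `synthetic_cohort` whose `$cohort` now carries the simulated
#'   alerts, plus `$truth` and `$central`
#' @export
simulate_registry <- function(params = cohort_params(),
                              behavior = lab_behavior(),
                              config = akival_config()) {
  gen <- generate_cohort(params)
  sim <- simulate_lab_alerts(gen$cohort, behavior, config)
  gen$cohort$alerts <- sim$alerts
  gen$truth <- sim$truth
  gen$central <- sim$central
  gen
}

#' Write a simulated cohort as fixture files
#'
#' Emits the submission CSV dialect consumed by [read_submission()]
#' (scr.csv, alerts.csv, plus krt.csv / lims.csv when present) and, for
#' `synthetic_cohort` inputs, truth.csv with the per-result ground truth.
#'
#' @param x `aki_cohort` or `synthetic_cohort`
#' @param dir output directory (created if needed)
#' @return invisibly, the directory
#' @export
write_fixture <- function(x, dir) {
  co <- if (inherits(x, "synthetic_cohort")) x$cohort else x
  stopifnot(inherits(co, "aki_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_submission(co, file.path(dir, "scr.csv"), file.path(dir, "alerts.csv"))
  if (!is.null(co$krt_start) && nrow(co$krt_start)) {
    fwrite(co$krt_start[, .(mpi, krt_start_date = format(krt_start_date))],
           file.path(dir, "krt.csv"), quote = FALSE)
  }
  if (!is.null(co$lims_map) && nrow(co$lims_map)) {
    fwrite(co$lims_map, file.path(dir, "lims.csv"), quote = FALSE)
  }
  if (inherits(x, "synthetic_cohort") && !is.null(x$truth)) {
    tr <- copy(x$truth)[, specimen_dt := format_dt(specimen_dt)]
    fwrite(tr, file.path(dir, "truth.csv"), quote = FALSE)
  }
  invisible(dir)
}
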