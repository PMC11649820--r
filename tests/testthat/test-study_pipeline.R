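mk_sim <- function(n = 80, seed = 41, behavior = lab_behavior(), ...) {
  simulate_registry(cohort_params(n_patients = n, months = 12, seed = seed, ...),
                    behavior)
}

test_that("pairing honours the live-date and alert-linkage rules", {
  res <- mk_results("P1", c(-40, 10, 30), c(60, 60, 150))
  al <- mk_alerts("P1", 10, 1) # live date = day 10; alert on a stage-0 result
  co <- cohort(res, al)
  pairs <- build_pairs(co)
  # day -40 precedes the live date and has no alert: no pair
  expect_equal(nrow(pairs), 2)
  # day 30: central stage 2 (150/60), no alert: pair (0, 2), inferred
  p30 <- pairs[specimen_dt == dt_at(30)]
  expect_equal(p30$local_stage, 0L)
  expect_equal(p30$central_stage, 2L)
  expect_true(p30$inferred)
  # covariates attached
  expect_equal(p30$baseline_scr, 60)      # rv2 preferred
  expect_equal(p30$year, 2019L)
  expect_equal(p30$age_at_test, 58L)
})

test_that("zero-corruption simulation closes the loop: agreement is exactly 1", {
  sim <- mk_sim()
  pairs <- build_pairs(sim$cohort, central = sim$central)
  expect_true(all(pairs$local_stage == pairs$central_stage))
  ov <- overall_analysis(pairs)
  expect_identical(ov$agreement$coefficient, 1)
  expect_identical(ov$agreement$pa, 1)
})

test_that("pooled matrix is the cellwise sum of per-lab matrices and analyses are order-invariant", {
  sim <- mk_sim(n = 100, seed = 42,
                behavior = lab_behavior(suppression_prob = 0.3))
  pairs <- build_pairs(sim$cohort, central = sim$central)
  pooled <- unclass(overall_analysis(pairs)$matrix)
  by_lab <- Reduce(`+`, lapply(unique(pairs$lab_code), function(l) {
    p <- pairs[lab_code == l]
    unclass(cross_tabulate(p$local_stage, p$central_stage))
  }))
  expect_equal(pooled, by_lab, ignore_attr = TRUE)

  # reordering the input rows changes nothing
  shuf <- sim$cohort
  shuf$results <- shuf$results[sample(nrow(shuf$results))]
  shuf$alerts <- shuf$alerts[sample(nrow(shuf$alerts))]
  pairs2 <- build_pairs(shuf)
  expect_equal(overall_analysis(pairs2)$agreement$coefficient,
               overall_analysis(pairs)$agreement$coefficient)
})

test_that("per-group analysis isolates a corrupted laboratory", {
  beh <- list(L01 = lab_behavior(suppression_prob = 0.6))
  sim <- mk_sim(n = 150, seed = 43, behavior = beh, n_labs = 2)
  pairs <- build_pairs(sim$cohort, central = sim$central)
  tab <- per_group_analysis(pairs, "lab")
  expect_equal(tab$group[1], "L01") # sorted ascending: corrupted lab first
  expect_lt(tab[group == "L01", coefficient], tab[group == "L02", coefficient])
  # labs without a LIMS entry pool into "Unknown"
  lims <- data.frame(lab_code = "L01", lims_provider = "LIMS1")
  lt <- per_group_analysis(pairs, "lims", lims_map = lims)
  expect_setequal(lt$group, c("LIMS1", "Unknown"))
})

test_that("complete-case sensitivity drops inferred zeros only", {
  sim <- mk_sim(n = 60, seed = 44)
  pairs <- build_pairs(sim$cohort, central = sim$central)
  cc <- sensitivity_complete_case(pairs)
  expect_equal(cc$n, sum(!pairs$inferred))
  # no inferred zeros present -> identical to overall
  sub <- pairs[inferred == FALSE]
  expect_equal(sensitivity_complete_case(sub)$coefficient,
               overall_analysis(sub)$agreement$coefficient)
  # all pairs inferred -> error
  expect_error(sensitivity_complete_case(pairs[inferred == TRUE]), "no pairs remain")
})

test_that("complete-months sensitivity excludes labs with dropped months", {
  # dense alerting so a faithful lab has alerts every month
  beh <- list(L02 = lab_behavior(monthly_missing_prob = 0.7))
  sim <- simulate_registry(cohort_params(n_patients = 150, months = 6,
                                         n_labs = 2, episode_rate = 3,
                                         seed = 45), beh)
  flags <- assess_monthly_completeness(sim$cohort)
  comp <- lab_completeness(flags)
  expect_true(comp[lab_code == "L01", complete])
  expect_false(comp[lab_code == "L02", complete])
  pairs <- build_pairs(sim$cohort, central = sim$central)
  out <- sensitivity_complete_months(pairs, flags)
  expect_true("L02" %in% out$labs_dropped)
  expect_equal(out$agreement$n,
               nrow(pairs[lab_code %in% out$labs_kept]))
  # with every lab complete the filter is the identity
  sim2 <- simulate_registry(cohort_params(n_patients = 80, months = 6,
                                          n_labs = 1, episode_rate = 3,
                                          seed = 46))
  pairs2 <- build_pairs(sim2$cohort, central = sim2$central)
  flags2 <- assess_monthly_completeness(sim2$cohort)
  expect_true(all(lab_completeness(flags2)$complete))
  out2 <- sensitivity_complete_months(pairs2, flags2)
  expect_equal(out2$agreement$coefficient,
               overall_analysis(pairs2)$agreement$coefficient)
})

test_that("subgroup analysis stratifies on within-sample quantiles", {
  sim <- mk_sim(n = 120, seed = 47)
  pairs <- build_pairs(sim$cohort, central = sim$central)
  sub <- subgroup_analysis(pairs, "baseline_scr")
  expect_lte(nrow(sub$results), 4)
  # near-equal occupancy
  expect_lt(diff(range(sub$results$n_pairs)) / mean(sub$results$n_pairs), 0.25)
  expect_equal(length(sub$cutpoints), 5)
  sub_age <- subgroup_analysis(pairs, "age")
  expect_lte(nrow(sub_age$results), 5)
  # degenerate input: warns
  w <- capture_warnings(subgroup_analysis(pairs[1:3], "age"))
  expect_true(any(grepl("too few", w)))
})

test_that("table 1 descriptives are additive and consistent", {
  sim <- mk_sim(n = 60, seed = 48)
  pairs <- build_pairs(sim$cohort, central = sim$central)
  t1 <- build_table1(sim$cohort, pairs, sim$central)
  g <- function(k) t1[metric == k, value]
  expect_equal(g("local_alerts_total"),
               g("local_stage1_n") + g("local_stage2_n") + g("local_stage3_n"))
  expect_equal(g("local_stage1_pct") + g("local_stage2_pct") + g("local_stage3_pct"),
               100, tolerance = 1e-9)
  # zero corruption: local and central alert counts coincide
  expect_equal(g("local_alerts_total"), g("central_alerts_total"))
  expect_equal(g("local_stage3_n"), g("central_stage3_n"))
  expect_equal(g("n_persons"), uniqueN(sim$cohort$results$mpi))
})

test_that("the committed smoke fixture reproduces its frozen analysis", {
  d <- system.file("extdata", "smoke", package = "akival")
  co <- read_submission(file.path(d, "scr.csv"), file.path(d, "alerts.csv"))
  expect_equal(nrow(co$results), 200)
  expect_equal(nrow(co$alerts), 22)
  pairs <- build_pairs(co)
  ov <- overall_analysis(pairs)
  expect_equal(nrow(pairs), 185)
  expect_equal(unname(unclass(ov$matrix)[1, ]), c(160L, 2L, 0L, 1L),
               ignore_attr = TRUE)
  expect_equal(ov$agreement$coefficient, 0.9908580888, tolerance = 1e-9)
  # full pipeline over the same files, via the input mode
  rep <- run_study(list(input = list(scr = file.path(d, "scr.csv"),
                                     alerts = file.path(d, "alerts.csv"))))
  expect_equal(rep$overall$coefficient, ov$agreement$coefficient)
})

test_that("run_study produces a deterministic report and matrix-only mode works", {
  cfg <- list(seed = 49,
              simulate = list(params = list(n_patients = 40, months = 6)))
  r1 <- run_study(cfg)
  r2 <- run_study(cfg)
  expect_equal(r1$overall$coefficient, r2$overall$coefficient)
  expect_equal(r1$table2, r2$table2)
  expect_s3_class(r1$table3, "data.table")
  expect_error(run_study(list(simulate = list(params = list(n_patients = 40,
                                                            months = 6,
                                                            episode_rate = 0,
                                                            tests_per_month = 0.01)))),
               "pairs|results|empty", ignore.case = TRUE)

  m <- unclass(ukrr_alert_matrix())
  rep_m <- run_study(list(matrix = m))
  expect_equal(round(rep_m$overall$coefficient, 2), 0.97)
  expect_equal(round(rep_m$sensitivity$complete_case$coefficient, 2), 0.83)
})
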