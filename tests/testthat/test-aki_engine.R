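cfg <- akival_config()

test_that("reference values honour the window conventions", {
  t0 <- dt_at(0)
  # rv1 = min over (t-7d, t)
  rv <- compute_reference_values(c(dt_at(-5), dt_at(-2), t0), c(60, 80, 90), 3)
  expect_equal(rv$rv1, 60)
  # odd-count median over [t-365d, t-7d]
  rv <- compute_reference_values(dt_at(c(-200, -100, -30, 0)), c(110, 90, 70, 95), 4)
  expect_equal(rv$rv2, 90)
  expect_true(is.na(rv$rv1))
  # even count: mean of middle two
  rv <- compute_reference_values(dt_at(c(-20, -10, 0)), c(100, 80, 95), 3)
  expect_equal(rv$rv2, 90)
  # nothing in the past 365 d
  rv <- compute_reference_values(dt_at(c(-400, 0)), c(70, 95), 2)
  expect_true(all(is.na(c(rv$rv1, rv$rv2, rv$min_48h))))
  # a result exactly 7 days old belongs to rv2, not rv1
  rv <- compute_reference_values(dt_at(c(-7, 0), hour = 9), c(60, 90), 2)
  expect_true(is.na(rv$rv1))
  expect_equal(rv$rv2, 60)
  # 48-h window is (t-48h, t)
  rv <- compute_reference_values(c(dt_at(-2, hour = 10), dt_at(0, hour = 9)), c(60, 90), 2)
  expect_equal(rv$min_48h, 60)
  rv <- compute_reference_values(c(dt_at(-2, hour = 8), dt_at(0, hour = 9)), c(60, 90), 2)
  expect_true(is.na(rv$min_48h))
})

test_that("staging rules fire on the documented boundaries", {
  s <- function(...) stage_result(...)
  # ratio 1.5 boundary is inclusive
  r <- s(90, list(rv1 = 60, rv2 = NA, min_48h = NA))
  expect_equal(r$stage, 1L)
  expect_equal(r$rule_fired, "ratio")
  # ratio 3.0 boundary
  expect_equal(s(180, list(rv1 = NA, rv2 = 60, min_48h = NA))$stage, 3L)
  # 48-h delta: strict > 26
  r <- s(120, list(rv1 = 100, rv2 = NA, min_48h = 90))
  expect_equal(r$stage, 1L)
  expect_equal(r$rule_fired, "delta48")
  expect_equal(s(125, list(rv1 = NA, rv2 = NA, min_48h = 100))$stage, 0L)
  expect_equal(s(127, list(rv1 = NA, rv2 = NA, min_48h = 100))$stage, 1L)
  # high-creatinine escalation (configurable)
  r <- s(360, list(rv1 = 200, rv2 = NA, min_48h = NA))
  expect_equal(r$stage, 3L)
  expect_equal(r$rule_fired, "high_c1")
  off <- akival_config(engine = list(high_c1_enabled = FALSE))
  expect_equal(s(360, list(rv1 = 200, rv2 = NA, min_48h = NA), off)$stage, 1L)
  # no reference data at all
  r <- s(500, list(rv1 = NA, rv2 = NA, min_48h = NA))
  expect_equal(r$stage, 0L)
  expect_equal(r$rule_fired, "none")
})

test_that("ratio_mode controls which reference value stages the result", {
  # rv1 ratio 1.2, rv2 ratio 2.0: "both" takes the larger
  r_both <- stage_result(120, list(rv1 = 100, rv2 = 60, min_48h = NA))
  expect_equal(r_both$stage, 2L)
  pref <- akival_config(engine = list(ratio_mode = "prefer_rv1"))
  expect_equal(stage_result(120, list(rv1 = 100, rv2 = 60, min_48h = NA), pref)$stage, 0L)
})

test_that("run_central_algorithm stages whole cohorts deterministically", {
  # single result -> stage 0
  co <- cohort(mk_results("P1", 0, 80))
  out <- run_central_algorithm(co)
  expect_equal(out$stage, 0L)
  expect_equal(out$rule_fired, "none")
  # flat series -> all zero
  co <- cohort(mk_results("P1", seq(0, 300, by = 30), 80))
  expect_true(all(run_central_algorithm(co)$stage == 0L))
  # injected 2.5x rise over rv2: baseline 60 at days -200..-30, peak 150
  co <- cohort(mk_results("P1", c(-200, -100, -30, 0), c(60, 60, 60, 150)))
  out <- run_central_algorithm(co)
  expect_equal(out[specimen_dt == dt_at(0), stage], 2L)
  expect_equal(out[specimen_dt == dt_at(0), ratio_rv2], 2.5)
  # output independent of on-disk row order
  res <- mk_results("P1", c(-200, -100, -30, 0), c(60, 60, 60, 150))
  out2 <- run_central_algorithm(cohort(res[sample(nrow(res)), ]))
  expect_equal(out, out2)
})

test_that("live dates are per-lab minima; labs without alerts are absent", {
  al <- rbind(mk_alerts("P1", 64, 1, lab = "L01"),   # 2019-03-06
              mk_alerts("P2", 60, 2, lab = "L01"),   # 2019-03-02
              mk_alerts("P3", 90, 3, lab = "L02"))
  co <- cohort(mk_results(c("P1", "P2", "P3"), 1, 80, lab = c("L01", "L01", "L02")), al)
  ld <- determine_live_dates(co$alerts)
  expect_equal(ld[lab_code == "L01", live_date], as.Date("2019-03-02"))
  expect_equal(nrow(ld), 2)
  expect_equal(nrow(determine_live_dates(cohort(mk_results("P", 0, 70))$alerts)), 0)
})

test_that("local stage inference matches alerts and infers zeros after live date", {
  res <- mk_results("P1", c(10, 20, 30), c(80, 160, 90))
  al <- mk_alerts("P1", 20, 2)
  co <- cohort(res, al)
  loc <- infer_local_stage(co)
  # result with matching alert
  expect_equal(loc[specimen_dt == dt_at(20), local_stage], 2L)
  expect_false(loc[specimen_dt == dt_at(20), inferred])
  # unalerted result before the live date: not evaluable
  expect_true(is.na(loc[specimen_dt == dt_at(10), local_stage]))
  # unalerted result after the live date: inferred zero
  expect_equal(loc[specimen_dt == dt_at(30), local_stage], 0L)
  expect_true(loc[specimen_dt == dt_at(30), inferred])

  # two alerts claiming one result: higher stage wins
  al2 <- rbind(mk_alerts("P1", 20, 1, hour = 8), mk_alerts("P1", 20, 3, hour = 10))
  loc2 <- infer_local_stage(cohort(res, al2))
  expect_equal(loc2[specimen_dt == dt_at(20), local_stage], 3L)

  # an alert is claimed by its nearest result, not by every result in tolerance
  res3 <- mk_results("P1", c(20, 21), c(160, 80), hour = c(9, 9))
  loc3 <- infer_local_stage(cohort(res3, al))
  expect_equal(loc3[specimen_dt == dt_at(20), local_stage], 2L)
  expect_equal(loc3[specimen_dt == dt_at(21), local_stage], 0L)
  expect_true(loc3[specimen_dt == dt_at(21), inferred])
})

test_that("staging is monotone in the index creatinine", {
  set.seed(11)
  for (i in 1:50) {
    rv <- list(rv1 = sample(c(NA, runif(1, 40, 150)), 1),
               rv2 = sample(c(NA, runif(1, 40, 150)), 1),
               min_48h = sample(c(NA, runif(1, 40, 150)), 1))
    c1 <- sort(runif(20, 20, 800))
    st <- stage_result(c1, rv)$stage
    expect_true(all(diff(st) >= 0))
  }
})

test_that("ratio-derived stages are scale invariant", {
  set.seed(12)
  cfg_no_hc <- akival_config(engine = list(high_c1_enabled = FALSE))
  for (i in 1:50) {
    rv1 <- runif(1, 40, 150)
    rv2 <- runif(1, 40, 150)
    c1 <- runif(1, 20, 500)
    k <- runif(1, 0.1, 10)
    s1 <- stage_result(c1, list(rv1 = rv1, rv2 = rv2, min_48h = NA), cfg_no_hc)$stage
    s2 <- stage_result(k * c1, list(rv1 = k * rv1, rv2 = k * rv2, min_48h = NA), cfg_no_hc)$stage
    expect_identical(s1, s2)
  }
})

test_that("engine agrees with the brute-force window oracle on random series", {
  set.seed(13)
  for (rep in 1:40) {
    m <- sample(1:10, 1)
    days <- sort(round(runif(m, -400, 0), 3))
    vals <- round(runif(m, 30, 500), 1)
    co <- cohort(mk_results("P1", days, vals))
    got <- run_central_algorithm(co)$stage
    want <- oracle_stage_series(days, vals)
    expect_identical(got, want)
  }
})
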