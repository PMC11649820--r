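test_that("ordinal weight family has the documented structure", {
  w <- ordinal_weights(4)
  expect_equal(diag(w), rep(1, 4), ignore_attr = TRUE)
  expect_equal(w[1, 2], 5 / 6)
  expect_equal(w[1, 3], 1 / 2)
  expect_equal(w[1, 4], 0)
  expect_true(isSymmetric(unname(w)))
  # q = 2 collapses to identity weights
  expect_equal(unname(ordinal_weights(2)), diag(2))
  expect_error(ordinal_weights(1), "at least 2")
  # any family: unit diagonal, [0,1] entries
  for (fam in c("linear", "quadratic", "identity")) {
    w <- ordinal_weights(5, fam)
    expect_equal(diag(w), rep(1, 5), ignore_attr = TRUE)
    expect_true(all(w >= 0 & w <= 1))
  }
})

test_that("published matrix reproduces the two reference coefficients", {
  m <- ukrr_alert_matrix()
  full <- gwet_ac1(m)
  expect_equal(round(full$coefficient, 2), 0.97)
  expect_equal(full$band, "almost perfect")
  mcc <- unclass(m)
  mcc[1, ] <- 0L
  cc <- gwet_ac1(mcc)
  expect_equal(round(cc$coefficient, 2), 0.83)
  # and only the combinatorial ordinal family reproduces both
  hits <- vapply(c("identity", "linear", "quadratic", "ordinal"), function(fam) {
    round(gwet_ac1(m, fam)$coefficient, 2) == 0.97 &&
      round(gwet_ac1(mcc, fam)$coefficient, 2) == 0.83
  }, logical(1))
  expect_identical(hits, c(identity = FALSE, linear = FALSE,
                           quadratic = FALSE, ordinal = TRUE))
})

test_that("coefficient hits its algebraic anchors", {
  # purely diagonal mass: pa = 1, coefficient = 1
  d <- diag(c(40, 25, 20, 15))
  ag <- gwet_ac1(d)
  expect_equal(ag$pa, 1)
  expect_equal(ag$coefficient, 1)
  # uniform 4x4 matrix, unweighted: pa = 1/4 and pe = 1/4 exactly, so 0
  u <- matrix(5, 4, 4)
  ag <- gwet_ac1(u, weights = "identity")
  expect_equal(ag$pa, 1 / 4)
  expect_equal(ag$pe, 1 / 4)
  expect_equal(ag$coefficient, 0)
  expect_error(gwet_ac1(matrix(0, 4, 4)), "empty")
})

test_that("percent positive agreement is the diagonal share", {
  expect_equal(percent_positive_agreement(diag(c(9, 5, 3, 1)))$unweighted, 1)
  z <- matrix(1, 4, 4) - diag(4) # zero diagonal
  expect_equal(percent_positive_agreement(z * 2)$unweighted, 0)
  ppa <- percent_positive_agreement(ukrr_alert_matrix())
  expect_equal(round(ppa$unweighted, 4), 0.9277)
})

test_that("Landis-Koch bands and acceptability follow the convention", {
  expect_equal(landis_koch_band(0.17), "slight")
  expect_equal(landis_koch_band(0.98), "almost perfect")
  expect_equal(landis_koch_band(0.61), "substantial")
  expect_equal(landis_koch_band(c(-0.5, 0, 0.2, 0.35, 0.5, 0.8)),
               c("poor", "slight", "slight", "fair", "moderate", "substantial"))
  expect_error(landis_koch_band(1.2), "outside")
  expect_true(gwet_ac1(diag(c(5, 5, 5, 5)))$acceptable)
})

test_that("cross_tabulate keeps all q categories and computes percents", {
  cm <- cross_tabulate(2, 2)
  expect_equal(dim(unclass(cm)), c(4, 4))
  expect_equal(unclass(cm)[3, 3], 1L)
  expect_equal(percents(cm)$percent[3, 3], 100)
  cm2 <- cross_tabulate(c(0, 0), c(0, 1))
  expect_equal(percents(cm2)$row_total[[1]], 2)
  expect_error(cross_tabulate(4, 1), "0..3")
})

test_that("matrix path agrees with the per-subject summation oracle", {
  set.seed(21)
  w <- ordinal_weights(4)
  for (rep in 1:25) {
    n <- sample(5:50, 1)
    a <- sample(0:3, n, replace = TRUE, prob = c(0.6, 0.2, 0.1, 0.1))
    b <- ifelse(runif(n) < 0.7, a, sample(0:3, n, replace = TRUE))
    got <- gwet_ac1(cross_tabulate(a, b), w)$coefficient
    expect_equal(got, oracle_gwet(a, b, w), tolerance = 1e-12)
  }
})

test_that("consistent relabeling leaves the coefficient unchanged", {
  set.seed(22)
  for (rep in 1:20) {
    m <- matrix(rpois(16, 8), 4, 4)
    w <- ordinal_weights(4)
    perm <- sample(4)
    g1 <- gwet_ac1(m, w)$coefficient
    g2 <- gwet_ac1(m[perm, perm], w[perm, perm])$coefficient
    expect_equal(g1, g2, tolerance = 1e-12)
  }
})

test_that("the standard error shrinks as 1/sqrt(n) under count scaling", {
  m <- matrix(c(80, 6, 2, 1, 5, 30, 3, 1, 2, 3, 20, 2, 1, 1, 2, 10), 4, 4)
  se1 <- gwet_ac1(m)$se
  se4 <- gwet_ac1(m * 4)$se
  # exact ratio is sqrt((n-1)/(4n-1)) ~ 1/2
  expect_equal(se4 / se1, 1 / 2, tolerance = 0.05)
  # bootstrap cross-check lands in the same range
  seb <- gwet_ac1(m, ci_method = "bootstrap", n_boot = 400, seed = 99)$se
  expect_lt(abs(seb - se1) / se1, 0.5)
})
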