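test_that("alpha is 1 for perfectly consistent items and matches the hand case", {
  m <- cbind(1:6, 1:6, 1:6)
  expect_equal(cronbach_alpha(m), 1)
  # shifted copies: still perfectly consistent
  expect_equal(cronbach_alpha(cbind(1:4, 2:5)), 1)
  expect_equal(cronbach_alpha(matrix(c(1, 2, 2, 3, 3, 4, 4, 5), ncol = 2, byrow = TRUE)), 1)
})

test_that("alpha of uncorrelated equal-variance items is near zero", {
  set.seed(101)
  m <- matrix(rnorm(10000 * 3), ncol = 3)
  expect_lt(abs(cronbach_alpha(m)), 0.05)
})

test_that("alpha agrees with the covariance-matrix oracle and rejects degenerates", {
  set.seed(102)
  for (rep in 1:20) {
    m <- matrix(sample(0:4, 15, replace = TRUE), ncol = 3)
    if (stats::var(rowSums(m)) == 0) next
    expect_equal(cronbach_alpha(m), oracle_alpha_cov(m), tolerance = 1e-12)
  }
  expect_error(cronbach_alpha(matrix(1, 4, 3)), "variance")
})

test_that("ICC forms behave analytically under identity and location shift", {
  x <- c(3, 7, 1, 9, 5)
  expect_equal(icc_single(cbind(x, x), "consistency"), 1)
  expect_equal(icc_single(cbind(x, x), "agreement"), 1)
  shifted <- cbind(x, x + 2)
  expect_equal(icc_single(shifted, "consistency"), 1)
  expect_lt(icc_single(shifted, "agreement"), 1)
})

test_that("ICC matches the explicit sums-of-squares oracle on random matrices", {
  set.seed(103)
  for (rep in 1:20) {
    m <- matrix(sample(0:12, 10, replace = TRUE), ncol = 2)
    if (oracle_two_way_ms(m)$msr == 0) next
    expect_equal(icc_single(m, "consistency"), oracle_icc(m, "consistency"),
                 tolerance = 1e-10)
    expect_equal(icc_single(m, "agreement"), oracle_icc(m, "agreement"),
                 tolerance = 1e-10)
  }
})

test_that("agreement is bounded by consistency exactly when the column variance dominates", {
  # with a positive numerator (MSR > MSE), the extra (k/n)(MSC - MSE) term
  # can only shrink the coefficient when MSC >= MSE
  set.seed(104)
  for (rep in 1:20) {
    subj <- rnorm(6, sd = 3)
    m <- cbind(subj + rnorm(6, sd = 0.5), subj + 1 + rnorm(6, sd = 0.5))
    ms <- oracle_two_way_ms(m)
    if (ms$msr > ms$mse && ms$msc >= ms$mse) {
      expect_lte(icc_single(m, "agreement"), icc_single(m, "consistency") + 1e-12)
    }
  }
  # constructed so that MSC = MSE exactly: the two forms coincide
  x <- c(0, 4, 8, 12)
  m_eq <- cbind(x, x + c(2, 0, 0, 0))
  ms <- oracle_two_way_ms(m_eq)
  expect_equal(ms$msc, ms$mse, tolerance = 1e-12)
  expect_equal(icc_single(m_eq, "agreement"), icc_single(m_eq, "consistency"),
               tolerance = 1e-12)
})

test_that("ICC rejects degenerate all-constant ratings", {
  expect_error(icc_single(matrix(5, 4, 2)), "degenerate")
})

test_that("CCC is exact on identity and reflected pairs", {
  x <- c(1, 4, 2, 8, 5, 7)
  expect_equal(lin_ccc(x, x)$ccc, 1)
  y <- -(x - mean(x)) # mean 0 after centering both
  xc <- x - mean(x)
  expect_equal(lin_ccc(xc, -xc)$ccc, -1)
})

test_that("CCC equals r times the bias-correction factor and is bounded by |r|", {
  set.seed(105)
  for (rep in 1:25) {
    x <- rnorm(15); y <- 0.5 * x + rnorm(15, sd = 0.7) + runif(1, -1, 1)
    got <- lin_ccc(x, y)$ccc
    expect_equal(got, oracle_ccc_rcb(x, y), tolerance = 1e-12)
    expect_lte(abs(got), abs(stats::cor(x, y)) + 1e-12)
  }
})

test_that("CCC decreases strictly under a location shift of one administration", {
  set.seed(106)
  x <- rnorm(30)
  y <- x + rnorm(30, sd = 0.1)
  base <- lin_ccc(x, y)$ccc
  for (shift in c(0.5, 1, 2)) {
    expect_lt(lin_ccc(x, y + shift)$ccc, base)
  }
})

test_that("alpha and ICC-consistency are invariant to a common additive constant", {
  set.seed(107)
  m <- matrix(rnorm(20), ncol = 2)
  expect_equal(icc_single(m + 7, "consistency"), icc_single(m, "consistency"),
               tolerance = 1e-12)
  m3 <- matrix(rnorm(30), ncol = 3)
  expect_equal(cronbach_alpha(m3 + 11), cronbach_alpha(m3), tolerance = 1e-12)
  # CCC too, when the constant is added to both sides
  expect_equal(lin_ccc(m[, 1] + 7, m[, 2] + 7)$ccc, lin_ccc(m[, 1], m[, 2])$ccc,
               tolerance = 1e-12)
})

test_that("widening the confidence level widens the CCC interval", {
  set.seed(108)
  x <- rnorm(20); y <- x + rnorm(20, sd = 0.5)
  ci90 <- lin_ccc(x, y, 0.90)
  ci99 <- lin_ccc(x, y, 0.99)
  expect_lt(ci99$ci_low, ci90$ci_low)
  expect_gt(ci99$ci_high, ci90$ci_high)
  expect_lte(ci90$ci_low, ci90$ccc)
  expect_gte(ci90$ccc, ci90$ci_low)
  expect_lte(ci90$ccc, ci90$ci_high)
})

test_that("CCC input contract is enforced", {
  expect_error(lin_ccc(1:5, 1:4), "equal length")
  expect_error(lin_ccc(c(1, 2), c(1, 2)), "n >= 3")
  expect_error(lin_ccc(rep(1, 5), rep(2, 5)), "zero variance")
})

test_that("a retest identical to the test yields unit reliability", {
  sim <- simulate_cohort(simulation_params(n_participants = 12, retest_rho = 1,
                                           report_noise = 0, seed = 21))
  rep <- reliability_report(sim$test, sim$retest)
  expect_equal(rep$totals$icc_consistency, 1)
  expect_equal(rep$totals$icc_agreement, 1)
  expect_equal(rep$totals$ccc, 1)
  expect_identical(rep$n, 12L)
  expect_lte(rep$alpha_r1, 1)
})

test_that("reliability_report rejects unmatched ids, listing the orphans", {
  sim <- simulate_cohort(simulation_params(n_participants = 4, seed = 22))
  retest <- sim$retest
  retest[[2]]$participant_id <- "GHOST"
  expect_error(reliability_report(sim$test, retest), "GHOST")
  expect_error(reliability_report(sim$test[1], sim$retest[1]), "at least 3")
})

test_that("reliability_report aligns pairs by id, not by position", {
  sim <- simulate_cohort(simulation_params(n_participants = 8, retest_rho = 1,
                                           report_noise = 0, seed = 23))
  shuffled <- sim$retest[c(3, 1, 4, 2, 8, 6, 5, 7)]
  rep <- reliability_report(sim$test, shuffled)
  expect_equal(rep$totals$ccc, 1)
})
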