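test_that("constant error follows its defining arithmetic", {
  ce <- constant_error(c(38, 40, 42), c(37, 41, 40))
  expect_equal(ce$ce, 2 / 3)
  expect_equal(ce$ce_sd, sqrt(7 / 3))
  expect_true(ce$ce_p > 0 && ce$ce_p < 1)

  id <- constant_error(c(38, 40, 42), c(38, 40, 42))
  expect_equal(id$ce, 0)
  expect_equal(id$ce_sd, 0)
  expect_true(is.na(id$ce_p))

  expect_error(constant_error(c(1, 2), c(1, 2)), "at least 3")
})

test_that("swapping measured and estimated negates CE, keeps SD and p", {
  set.seed(11)
  for (k in 1:20) {
    p <- random_pairs()
    a <- constant_error(p$m, p$e)
    b <- constant_error(p$e, p$m)
    expect_equal(b$ce, -a$ce)
    expect_equal(b$ce_sd, a$ce_sd)
    expect_equal(b$ce_p, a$ce_p)
  }
})

test_that("SEE follows its closed form and limit cases", {
  # hand-computed: r = 3 / (2 sqrt(13/3)), SEE = 10 / sqrt(52)
  expect_equal(standard_error_of_estimate(c(38, 40, 42), c(37, 41, 40)),
               10 / sqrt(52), tolerance = 1e-12)

  # perfectly correlated estimates: SEE = 0
  m <- c(30, 35, 40, 45)
  expect_equal(standard_error_of_estimate(m, 3 + 0.8 * m), 0,
               tolerance = 1e-9)

  # near-uncorrelated estimates: SEE approaches SD of measured
  set.seed(22)
  m2 <- rnorm(4000, 38, 6.6)
  e2 <- rnorm(4000, 38, 5)
  expect_equal(standard_error_of_estimate(m2, e2), sd(m2),
               tolerance = 0.01)

  expect_error(standard_error_of_estimate(c(1, 1, 1), c(1, 2, 3)),
               "zero variance")
})

test_that("total error is the RMS difference", {
  expect_equal(total_error(c(38, 40, 42), c(37, 41, 40)), sqrt(2))
  expect_equal(total_error(c(38, 40), c(38, 40)), 0)
})

test_that("TE dominates SEE and |CE|, and the RMSE decomposition holds", {
  set.seed(33)
  for (k in 1:100) {
    p <- random_pairs()
    te <- total_error(p$m, p$e)
    ce <- constant_error(p$m, p$e)
    # TE^2 is at least the (df-corrected) SEE^2: the SEE is the residual
    # scatter of the best affine recalibration (sample SD, n-1), while TE
    # charges the identity calibration and divides by n
    see <- standard_error_of_estimate(p$m, p$e)
    expect_gte(te^2 + 1e-12, (p$n - 1) / p$n * see^2)
    expect_gte(te, abs(ce$ce))
    expect_equal(te^2, ce$ce^2 + (p$n - 1) / p$n * ce$ce_sd^2,
                 tolerance = 1e-9)
  }
})

test_that("SEE alone is invariant to positive affine recalibration", {
  set.seed(44)
  p <- random_pairs(40)
  e2 <- 5 + 1.7 * p$e
  expect_equal(standard_error_of_estimate(p$m, e2),
               standard_error_of_estimate(p$m, p$e), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(total_error(p$m, e2),
                                total_error(p$m, p$e))))
  expect_false(isTRUE(all.equal(constant_error(p$m, e2)$ce,
                                constant_error(p$m, p$e)$ce)))
})

test_that("Bland-Altman bias mirrors CE and brackets it with the LoA", {
  set.seed(55)
  for (k in 1:50) {
    p <- random_pairs()
    ba <- bland_altman(p$m, p$e)
    ce <- constant_error(p$m, p$e)
    expect_identical(ba$fixed_bias, -ce$ce)
    expect_equal(ba$fixed_p, ce$ce_p)
    expect_lte(ba$loa_low, ba$fixed_bias)
    expect_gte(ba$loa_high, ba$fixed_bias)
    expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * sd(p$e - p$m))
  }
})

test_that("a constant offset gives an exact bias and no proportional term", {
  m <- c(38, 40, 42, 44)
  ba <- bland_altman(m, m + 2)
  expect_identical(ba$fixed_bias, 2)
  expect_identical(ba$fixed_sd, 0)
  expect_true(is.na(ba$prop_bias_r))
  expect_match(ba$prop_reason, "constant")
})

test_that("injected proportional structure is recovered with its sign", {
  # underestimation growing with fitness must surface as negative r:
  # d = estimated - measured falls as the pair mean rises
  set.seed(66)
  mean_vo2 <- rnorm(600, 38, 6.6)
  est <- mean_vo2 - 0.5 * (mean_vo2 - 38) + rnorm(600, 0, 1)
  ba <- bland_altman(mean_vo2, est)
  expect_lt(ba$prop_bias_r, 0)
  expect_lt(ba$prop_bias_p, 0.01)

  # inject_residual_structure: negative b1 at large n -> negative r
  # (both the planted term and the shared-noise component point down)
  base <- rnorm(2000, 38, 5)
  pc <- inject_residual_structure(base, b1 = -0.3, sigma_e = 4, seed = 7)
  ba2 <- bland_altman(pc)
  expect_lt(ba2$prop_bias_r, 0)
  expect_lt(ba2$prop_bias_p, 0.05)
})

test_that("fixed-bias recovery from the injection is exact without noise", {
  pc <- inject_residual_structure(c(35, 40, 45, 50), b0 = 2)
  ba <- bland_altman(pc)
  expect_identical(ba$fixed_bias, -2)
})

test_that("compare_methods drops incomplete pairs per method and reports", {
  d <- data.frame(id = 1:6, measured = c(38, 40, 42, 36, 44, 39),
                  a = c(37, 41, 40, 35, 45, 40),
                  b = c(37, NA, 40, 35, NA, 40))
  cmp <- compare_methods(d, measured = "measured",
                         estimates = c(A = "a", B = "b"))
  expect_identical(cmp$reports$A$n, 6L)
  expect_identical(cmp$reports$B$n, 4L)
  expect_identical(unname(cmp$dropped["B"]), 2L)

  # identical estimate columns give identical reports
  d2 <- data.frame(measured = c(38, 40, 42, 36), a = c(37, 41, 40, 33),
                   b = c(37, 41, 40, 33))
  cmp2 <- compare_methods(d2, measured = "measured",
                          estimates = c(A = "a", B = "b"))
  ra <- cmp2$reports$A; ra$method <- ""
  rb <- cmp2$reports$B; rb$method <- ""
  expect_identical(ra, rb)

  # methods with too few complete pairs are skipped with a warning
  d3 <- data.frame(measured = c(38, 40, 42), a = c(37, 41, 40),
                   b = c(37, NA, NA))
  expect_warning(cmp3 <- compare_methods(d3, measured = "measured",
                                         estimates = c(A = "a", B = "b")),
                 "complete pairs")
  expect_named(cmp3$reports, "A")
})

test_that("report invariants hold on random cohorts", {
  set.seed(77)
  for (k in 1:20) {
    p <- random_pairs()
    r <- agreement_report(p$m, p$e)
    expect_identical(r$fixed_bias, -r$ce)
    expect_gte(r$te, 0)
    expect_gte(r$see, 0)
    expect_equal(r$te^2, r$ce^2 + (r$n - 1) / r$n * r$ce_sd^2,
                 tolerance = 1e-9)
  }
})
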