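test_that("regression equation reproduces independent hand arithmetic", {
  # intercept only
  expect_identical(mrm_evaluate(0, 0, 0, 0, 0), 64.22)

  # reference-population per-sex means
  p_f <- participant("F", 48.3, "female", bmi = 21.6, pa_score = 8.6)
  expect_equal(estimate_mrm(p_f, hr_index = 46.9)$evo2max, 33.991,
               tolerance = 1e-9)
  p_m <- participant("M", 48.3, "male", bmi = 24.6, pa_score = 11.9)
  expect_equal(estimate_mrm(p_m, hr_index = 35.4)$evo2max, 40.718,
               tolerance = 1e-9)
})

test_that("regression output moves monotonically in each predictor", {
  base <- mrm_evaluate(45, 0, 23, 10, 40)
  expect_lt(mrm_evaluate(46, 0, 23, 10, 40), base)      # older -> lower
  expect_lt(mrm_evaluate(45, 0, 24, 10, 40), base)      # higher BMI -> lower
  expect_lt(mrm_evaluate(45, 0, 23, 10, 41), base)      # higher index -> lower
  expect_gt(mrm_evaluate(45, 0, 23, 11, 40), base)      # more active -> higher
  expect_equal(mrm_evaluate(45, 1, 23, 10, 40) - base, 5.74)
})

test_that("regression estimate is missing with a reason after a skip", {
  p <- default_participant()
  r <- step_record(70, 100, 150, hr_rec1 = 120, hr_rec2 = 100,
                   stage3_skipped = TRUE)
  res <- estimate_mrm(p, record = r)
  expect_true(is.na(res$evo2max))
  expect_match(res$reason, "stage 3 skipped")
})

test_that("extrapolation line recovers exactly collinear stage HRs", {
  # female constants x = (4,13,19,22,17,8); HR = 60 + 3x
  r <- step_record(72, 99, 117, 126, hr_rec1 = 111, hr_rec2 = 84)
  fit <- fit_lem_line(r, "female")
  expect_equal(fit$slope, 3, tolerance = 1e-12)
  expect_equal(fit$intercept, 60, tolerance = 1e-12)
  expect_identical(fit$n_points, 6L)
})

test_that("extrapolation line matches the normal-equations oracle", {
  set.seed(202)
  for (k in 1:200) {
    skip3 <- runif(1) < 0.2
    r <- random_step_record(skip = skip3)
    sex <- sample(c("female", "male"), 1)
    fit <- fit_lem_line(r, sex)
    x <- as.numeric(lem_constants(sex))
    y <- c(r$hr_rest, r$hr_ex1, r$hr_ex2, r$hr_ex3, r$hr_rec1, r$hr_rec2)
    if (skip3) { x <- x[-4]; y <- y[-4] }
    o <- lsq_oracle(x, y)
    expect_equal(fit$slope, o[["slope"]], tolerance = 1e-9)
    expect_equal(fit$intercept, o[["intercept"]], tolerance = 1e-9)
    expect_identical(fit$n_points, if (skip3) 5L else 6L)
  }
})

test_that("extrapolation reads VO2max off the line at the predicted max HR", {
  r <- step_record(72, 99, 117, 126, hr_rec1 = 111, hr_rec2 = 84)
  p40 <- default_participant(age = 40)
  res <- estimate_lem(p40, r)
  expect_equal(res$evo2max, (180 - 60) / 3, tolerance = 1e-12)
  expect_equal(res$predicted_max_hr, 180)

  p60 <- default_participant(age = 60)
  res60 <- estimate_lem(p60, r)
  expect_equal(res60$evo2max, (166 - 60) / 3, tolerance = 1e-12)

  # fox anchor on request
  res_fox <- estimate_lem(p60, r, formula = "fox")
  expect_equal(res_fox$evo2max, (160 - 60) / 3, tolerance = 1e-12)
})

test_that("flat or inverted HR responses refuse to extrapolate", {
  flat <- step_record(100, 100, 100, 100, hr_rec1 = 100, hr_rec2 = 100)
  fit <- fit_lem_line(flat, "female")
  expect_equal(fit$slope, 0)
  res <- estimate_lem(default_participant(), flat)
  expect_true(is.na(res$evo2max))
  expect_match(res$reason, "slope")
})

test_that("raising all HRs by a constant lowers the extrapolated VO2max", {
  set.seed(303)
  for (k in 1:25) {
    r <- random_step_record()
    fit <- fit_lem_line(r, "male")
    if (fit$slope <= 0.1) next
    shift <- runif(1, 1, 15)
    r2 <- step_record(r$hr_rest + shift, r$hr_ex1 + shift,
                      r$hr_ex2 + shift, r$hr_ex3 + shift,
                      r$hr_rec1 + shift, r$hr_rec2 + shift)
    p <- default_participant(sex = "male")
    v1 <- estimate_lem(p, r)$evo2max
    v2 <- estimate_lem(p, r2)$evo2max
    fit2 <- fit_lem_line(r2, "male")
    expect_equal(fit2$slope, fit$slope, tolerance = 1e-9)
    expect_equal(fit2$intercept, fit$intercept + shift, tolerance = 1e-9)
    expect_lt(v2, v1)
  }
})

test_that("combined rule returns exactly one leg, chosen by the cutoff", {
  set.seed(404)
  for (k in 1:50) {
    p <- default_participant(age = runif(1, 30, 60),
                             sex = sample(c("female", "male"), 1),
                             bmi = runif(1, 18, 30), pa = runif(1, 0, 44))
    r <- random_step_record()
    cutoff <- runif(1, 30, 50)
    mrm <- estimate_mrm(p, record = r)
    lem <- estimate_lem(p, r)
    comb <- estimate_combined(p, r, cutoff = cutoff)
    expect_identical(comb$switched_to_lem, mrm$evo2max >= cutoff)
    if (comb$switched_to_lem) {
      expect_identical(comb$evo2max, lem$evo2max)
      expect_identical(comb$lem_slope, lem$lem_slope)
      expect_identical(comb$lem_intercept, lem$lem_intercept)
    } else {
      expect_identical(comb$evo2max, mrm$evo2max)
    }
  }
})

test_that("combined rule boundary and degenerate cutoffs behave as documented", {
  p <- default_participant()
  r <- random_step_record()
  mrm_val <- estimate_mrm(p, record = r)$evo2max
  # inclusive comparison at exactly the cutoff takes the extrapolation leg
  comb_eq <- estimate_combined(p, r, cutoff = mrm_val)
  expect_true(comb_eq$switched_to_lem)
  # strict comparison at exactly the cutoff stays on the regression leg
  comb_strict <- estimate_combined(p, r, cutoff = mrm_val,
                                   cutoff_strict = TRUE)
  expect_false(comb_strict$switched_to_lem)
  # cutoff = +Inf makes combined identical to the regression leg
  comb_inf <- estimate_combined(p, r, cutoff = Inf)
  expect_false(comb_inf$switched_to_lem)
  expect_identical(comb_inf$evo2max, mrm_val)
})

test_that("a failing extrapolation leg propagates, never silently falls back", {
  p <- default_participant()
  flat <- step_record(100, 100, 100, 100, hr_rec1 = 100, hr_rec2 = 100)
  # force the switch with a tiny cutoff
  comb <- estimate_combined(p, flat, cutoff = 0.001)
  expect_true(comb$switched_to_lem)
  expect_true(is.na(comb$evo2max))
  expect_match(comb$reason, "LEM leg after switch")
})
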