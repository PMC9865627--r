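test_that("heart-rate index follows its defining arithmetic", {
  r <- step_record(70, hr_ex1 = 100, hr_ex2 = 125, hr_ex3 = 150,
                   hr_rec1 = 120, hr_rec2 = 100)
  expect_equal(hr_index(r), 70)  # (150-100) + (120-100)

  # recovery term may be negative
  r2 <- step_record(70, hr_ex1 = 110, hr_ex2 = 125, hr_ex3 = 140,
                    hr_rec1 = 115, hr_rec2 = 120)
  expect_equal(hr_index(r2), 25)

  # flat exercise and recovery responses cancel
  r3 <- step_record(70, hr_ex1 = 120, hr_ex2 = 120, hr_ex3 = 120,
                    hr_rec1 = 95, hr_rec2 = 95)
  expect_equal(hr_index(r3), 0)
})

test_that("heart-rate index is undefined after a stage-3 skip", {
  r <- step_record(70, 100, 150, hr_rec1 = 120, hr_rec2 = 100,
                   stage3_skipped = TRUE, rpe_end_stage2 = 18)
  idx <- hr_index(r)
  expect_true(is.na(idx))
  expect_match(attr(idx, "reason"), "stage 3 skipped")
})

test_that("heart-rate index is invariant to a uniform HR shift", {
  set.seed(101)
  for (k in 1:25) {
    r <- random_step_record()
    c_shift <- runif(1, -20, 20)
    r2 <- step_record(r$hr_rest + c_shift, r$hr_ex1 + c_shift,
                      r$hr_ex2 + c_shift, r$hr_ex3 + c_shift,
                      r$hr_rec1 + c_shift, r$hr_rec2 + c_shift)
    expect_equal(hr_index(r2), hr_index(r))
  }
})

test_that("the two max-HR formulas agree at 40 and diverge as stated", {
  expect_equal(predicted_max_hr(40, "fox"), 180)
  expect_equal(predicted_max_hr(40, "tanaka"), 180)
  expect_equal(predicted_max_hr(48.3, "tanaka"), 174.19)
  ages <- seq(20, 80, by = 0.5)
  tk <- predicted_max_hr(ages, "tanaka")
  fx <- predicted_max_hr(ages, "fox")
  expect_true(all(tk[ages > 40] > fx[ages > 40]))
  expect_true(all(tk[ages < 40] < fx[ages < 40]))
  expect_error(predicted_max_hr(0, "fox"), "positive")
})

test_that("stage-3 skip rule is the conjunction of its two criteria", {
  # 0.8 * (220 - 40) = 144
  expect_true(check_stage3_skip(150, 18, 40))
  expect_false(check_stage3_skip(143.9, 20, 40))   # HR criterion fails
  expect_false(check_stage3_skip(170, 12, 40))     # RPE criterion fails
  expect_true(check_stage3_skip(144, 17, 40))      # thresholds inclusive
  expect_warning(out <- check_stage3_skip(170, NA, 40), "RPE")
  expect_false(out)
})

test_that("maximal-effort verification counts three of four criteria", {
  # age 45: fox prediction 175, |178 - 175| <= 10 -> 3 of 4
  t1 <- treadmill_record(50, rer_max = 1.15, hr_max_observed = 178,
                         rpe_max = 19, plateau = FALSE)
  v1 <- verify_max_effort(t1, age = 45)
  expect_true(v1$met)
  expect_identical(sum(v1$criteria), 3L)

  t2 <- treadmill_record(50, rer_max = 1.05, hr_max_observed = 150,
                         rpe_max = 15, plateau = FALSE)
  v2 <- verify_max_effort(t2, age = 40)
  expect_false(v2$met)
  expect_identical(sum(v2$criteria), 0L)

  t3 <- treadmill_record(50, rer_max = 1.11, hr_max_observed = 180,
                         rpe_max = 18, plateau = TRUE)
  v3 <- verify_max_effort(t3, age = 40)
  expect_true(v3$met)
  expect_identical(sum(v3$criteria), 4L)

  # RPE threshold is strict (> 17), unlike the skip rule's inclusive 17
  t4 <- treadmill_record(50, rer_max = 1.15, hr_max_observed = 180,
                         rpe_max = 17, plateau = FALSE)
  expect_false(verify_max_effort(t4, age = 40)$criteria[["rpe"]])
})

test_that("satisfying more criteria never flips a pass into a fail", {
  base <- treadmill_record(50, rer_max = 1.15, hr_max_observed = 178,
                           rpe_max = 19, plateau = FALSE)
  better <- treadmill_record(50, rer_max = 1.15, hr_max_observed = 178,
                             rpe_max = 19, plateau = TRUE)
  v_base <- verify_max_effort(base, 45)
  v_better <- verify_max_effort(better, 45)
  expect_true(all(v_better$criteria >= v_base$criteria))
  expect_true(v_better$met >= v_base$met)
})
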