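# Independent least-squares oracle: normal equations solved directly,
# never sharing code with fit_lem_line().
lsq_oracle <- function(x, y) {
  n <- length(x)
  A <- matrix(c(n, sum(x), sum(x), sum(x * x)), 2, 2)
  beta <- solve(A, c(sum(y), sum(x * y)))
  c(intercept = beta[1], slope = beta[2])
}

# random plausible step record (continuous HRs in a safe window)
random_step_record <- function(skip = FALSE) {
  step_record(
    hr_rest = runif(1, 55, 90),
    hr_ex1 = runif(1, 80, 120),
    hr_ex2 = runif(1, 90, 150),
    hr_ex3 = if (skip) NULL else runif(1, 100, 180),
    hr_rec1 = runif(1, 80, 150),
    hr_rec2 = runif(1, 60, 130),
    stage3_skipped = skip
  )
}

random_pairs <- function(n = NULL) {
  if (is.null(n)) n <- sample(3:50, 1)
  m <- rnorm(n, 38, 6.6)
  e <- m + rnorm(n, runif(1, -2, 2), runif(1, 0.5, 6))
  list(m = m, e = e, n = n)
}

default_participant <- function(age = 40, sex = "female", bmi = 22,
                                pa = 10) {
  participant("T1", age = age, sex = sex, bmi = bmi, pa_score = pa)
}
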