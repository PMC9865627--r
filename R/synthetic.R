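# truncated-normal moments and moment matching -------------------------------

# mean/sd of Normal(mu, sigma) truncated to [a, b]
truncnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  z <- pnorm(be) - pnorm(al)
  dphi <- dnorm(al) - dnorm(be)
  m <- mu + sigma * dphi / z
  v <- sigma^2 * (1 + (al * dnorm(al) - be * dnorm(be)) / z - (dphi / z)^2)
  c(mean = m, sd = sqrt(v))
}

#' Parent parameters of a moment-matched truncated normal
#'
#' Finds (mu, sigma) of a parent normal such that its truncation to
#' \[a, b\] has the requested mean and standard deviation. Used so that a
#' bounded score (e.g. the 0–44 physical-activity score) is simulated with
#' exactly the observed marginal moments rather than the moments of an
#' unbounded parent — near a bound the two differ materially.
#'
#' @param target_mean,target_sd moments the truncated distribution must
#'   have.
#' @param a,b truncation bounds.
#' @return named numeric vector `c(mu, sigma)`.
#' @export
match_truncnorm <- function(target_mean, target_sd, a, b) {
  obj <- function(par) {
    mom <- truncnorm_moments(par[1], exp(par[2]), a, b)
    (mom[["mean"]] - target_mean)^2 + (mom[["sd"]] - target_sd)^2
  }
  fit <- optim(c(target_mean, log(target_sd)), obj,
               control = list(reltol = 1e-14, maxit = 5000))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# rejection sampler for the truncated normal; cap guards degenerate configs
rtruncnorm_reject <- function(n, mu, sigma, a, b, cap = 1000) {
  mu <- rep_len(mu, n)
  sigma <- rep_len(sigma, n)
  if (all(sigma == 0)) return(pmin(pmax(mu, a), b))
  out <- rnorm(n, mu, sigma)
  for (i in seq_len(cap)) {
    bad <- which(out < a | out > b)
    if (!length(bad)) return(out)
    out[bad] <- rnorm(length(bad), mu[bad], sigma[bad])
  }
  stop("truncated-normal rejection sampling exceeded the draw cap",
       call. = FALSE)
}

# configuration ---------------------------------------------------------------

#' Configuration of the synthetic cohort generator
#'
#' Defaults encode the sex-stratified population the estimators were
#' validated on: working adults with means/SDs of age 48.3 ± 7.0 (female) /
#' 48.3 ± 6.9 (male) years, BMI 21.6 ± 3.2 / 24.6 ± 2.9 kg·m⁻², PA score
#' 8.6 ± 7.5 / 11.9 ± 7.9 points (truncated to 0–44, moment-matched; see
#' [match_truncnorm()]), and VO2max 34.4 ± 5.0 / 41.2 ± 6.3 mL·kg⁻¹·min⁻¹,
#' with 68/128 of participants male.
#'
#' The remaining knobs govern structure the population table cannot supply:
#' resting heart rate 70 ± 8 bpm; per-stage heart-rate noise `sigma_hr`
#' (3 bpm); the SD of each individual's true maximal heart rate around the
#' tanaka age prediction, `sigma_max_hr` (10 bpm) — the documented
#' unreliability of age-predicted maxima, and the lever that makes the
#' extrapolation estimator the noisier one; and the measurement model for
#' the treadmill value, `measured = F + b0 + b1 (F − mean F) + e` with
#' residual SD `sigma_e` (4.2 mL·kg⁻¹·min⁻¹). Predictors are drawn
#' independently: only the marginals of the reference population are known,
#' so no correlation structure is asserted by default.
#'
#' @param n cohort size.
#' @param male_fraction probability a participant is male.
#' @param seed integer seed used by [generate_cohort()] (`NULL` = leave the
#'   RNG state alone).
#' @param age,bmi,pa,vo2max per-sex `c(mean, sd)` blocks (lists with
#'   `female`/`male`).
#' @param pa_bounds truncation bounds of the PA score.
#' @param hr_rest `c(mean, sd)` of resting heart rate, bpm.
#' @param sigma_hr per-stage heart-rate noise SD, bpm.
#' @param sigma_max_hr SD of true maximal heart rate around the tanaka
#'   prediction, bpm.
#' @param measurement `c(b0, b1, sigma_e)` of the treadmill measurement
#'   model.
#' @param max_hr_formula formula anchoring each individual's true maximal
#'   heart rate.
#' @param draw_cap resampling cap for invalid draws.
#' @return a list of class `"cohort_config"`.
#' @export
cohort_config <- function(n = 128, male_fraction = 68 / 128, seed = NULL,
                          age = list(female = c(mean = 48.3, sd = 7.0),
                                     male = c(mean = 48.3, sd = 6.9)),
                          bmi = list(female = c(mean = 21.6, sd = 3.2),
                                     male = c(mean = 24.6, sd = 2.9)),
                          pa = list(female = c(mean = 8.6, sd = 7.5),
                                    male = c(mean = 11.9, sd = 7.9)),
                          vo2max = list(female = c(mean = 34.4, sd = 5.0),
                                        male = c(mean = 41.2, sd = 6.3)),
                          pa_bounds = c(0, 44),
                          hr_rest = c(mean = 70, sd = 8),
                          sigma_hr = 3, sigma_max_hr = 10,
                          measurement = c(b0 = 0, b1 = 0, sigma_e = 4.2),
                          max_hr_formula = c("tanaka", "fox"),
                          draw_cap = 1000) {
  stopifnot(n >= 1, male_fraction >= 0, male_fraction <= 1,
            sigma_hr >= 0, sigma_max_hr >= 0, hr_rest[["sd"]] >= 0,
            measurement[["sigma_e"]] >= 0, pa_bounds[1] < pa_bounds[2])
  max_hr_formula <- match.arg(max_hr_formula)
  structure(list(n = as.integer(n), male_fraction = male_fraction,
                 seed = seed, age = age, bmi = bmi, pa = pa,
                 vo2max = vo2max, pa_bounds = pa_bounds, hr_rest = hr_rest,
                 sigma_hr = sigma_hr, sigma_max_hr = sigma_max_hr,
                 measurement = measurement,
                 max_hr_formula = max_hr_formula, draw_cap = draw_cap),
            class = "cohort_config")
}

# generation ------------------------------------------------------------------

by_sex <- function(block, sex, what) {
  vapply(sex, function(s) block[[s]][[what]], numeric(1))
}

#' Generate a synthetic step-test cohort
#'
#' Simulates a cohort with the statistical structure the estimators assume,
#' one flat table per the cohort file schema (see [read_cohort()]). Per
#' participant:
#'
#' 1. sex, age, BMI and PA score are drawn from the configured per-sex
#'    marginals (PA by moment-matched truncated normal);
#' 2. a true fitness `F` (VO2max) is drawn from the sex's distribution;
#' 3. a true maximal heart rate is drawn around the age prediction
#'    (`sigma_max_hr`), and a resting heart rate around its mean;
#' 4. stage heart rates are placed on the participant's own line through
#'    (stage VO2 constant, HR) — slope
#'    `(true max HR − resting HR) / (F − rest constant)` — plus independent
#'    per-stage noise `sigma_hr`. The linear extrapolation estimator is
#'    therefore approximately unbiased by construction, and the heart-rate
#'    index falls with fitness;
#' 5. the treadmill-measured VO2max is
#'    `F + b0 + b1 (F − population mean F) + Normal(0, sigma_e)`.
#'
#' Draws yielding a non-positive heart-rate slope (fitness at or below the
#' resting VO2 constant, or maximal HR at or below resting HR) or any stage
#' heart rate outside the plausibility window \[30, 230\] bpm are resampled
#' up to `draw_cap` times, then the generator errors. Output is
#' deterministic given `config$seed`.
#'
#' The table also carries the simulation truth (`true_fitness`,
#' `true_max_hr`, `true_hr_slope`) and plausible treadmill verification
#' fields (`rer_max`, `hr_max_observed`, `rpe_max`, `plateau`) so that
#' maximal-effort checks can be exercised; the full configuration is
#' attached as attribute `"config"`.
#'
#' @param config a [cohort_config()].
#' @param seed overrides `config$seed` when given.
#' @return a `data.frame` with one row per participant.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n = 5, seed = 1))
#' coh[, c("id", "sex", "age", "bmi", "vo2max_measured")]
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n

  sex <- ifelse(runif(n) < config$male_fraction, "male", "female")
  age <- rnorm(n, by_sex(config$age, sex, "mean"),
               by_sex(config$age, sex, "sd"))
  age <- pmin(pmax(age, 18), 90)  # keep ages adult; tails are irrelevant
  bmi <- rtruncnorm_reject(n, by_sex(config$bmi, sex, "mean"),
                           by_sex(config$bmi, sex, "sd"), 12, 60,
                           cap = config$draw_cap)

  pa_par <- lapply(c(female = "female", male = "male"), function(s)
    match_truncnorm(config$pa[[s]][["mean"]], config$pa[[s]][["sd"]],
                    config$pa_bounds[1], config$pa_bounds[2]))
  pa <- rtruncnorm_reject(
    n, vapply(sex, function(s) pa_par[[s]][["mu"]], numeric(1)),
    vapply(sex, function(s) pa_par[[s]][["sigma"]], numeric(1)),
    config$pa_bounds[1], config$pa_bounds[2], cap = config$draw_cap)

  draw_physio <- function(idx) {
    k <- length(idx)
    list(fitness = rnorm(k, by_sex(config$vo2max, sex[idx], "mean"),
                         by_sex(config$vo2max, sex[idx], "sd")),
         max_hr = predicted_max_hr(age[idx], config$max_hr_formula) +
           rnorm(k, 0, config$sigma_max_hr),
         rest_hr = rnorm(k, config$hr_rest[["mean"]],
                         config$hr_rest[["sd"]]))
  }

  x_rest <- 4  # resting VO2 constant, shared by both sexes
  fitness <- max_hr <- rest_hr <- numeric(n)
  hrs <- matrix(NA_real_, n, 6,
                dimnames = list(NULL, c("hr_rest", "hr_ex1", "hr_ex2",
                                        "hr_ex3", "hr_rec1", "hr_rec2")))
  pending <- seq_len(n)
  for (it in seq_len(config$draw_cap)) {
    if (!length(pending)) break
    ph <- draw_physio(pending)
    fitness[pending] <- ph$fitness
    max_hr[pending] <- ph$max_hr
    rest_hr[pending] <- ph$rest_hr
    slope <- (ph$max_hr - ph$rest_hr) / (ph$fitness - x_rest)
    for (j in seq_along(pending)) {
      i <- pending[j]
      xs <- lem_constants(sex[i])
      hrs[i, ] <- rest_hr[i] + slope[j] * (xs - x_rest) +
        rnorm(6, 0, config$sigma_hr)
    }
    ok <- ph$fitness > x_rest & ph$max_hr > ph$rest_hr &
      apply(hrs[pending, , drop = FALSE], 1,
            function(h) all(h >= 30 & h <= 230))
    pending <- pending[!ok]
  }
  if (length(pending))
    stop("cohort generation exceeded the draw cap; ",
         "check the configured distributions", call. = FALSE)

  slope_i <- (max_hr - rest_hr) / (fitness - x_rest)
  mm <- config$measurement
  pop_mean_f <- config$male_fraction * config$vo2max$male[["mean"]] +
    (1 - config$male_fraction) * config$vo2max$female[["mean"]]
  measured <- fitness + mm[["b0"]] + mm[["b1"]] * (fitness - pop_mean_f) +
    rnorm(n, 0, mm[["sigma_e"]])

  # plausible treadmill verification fields
  rer_max <- pmax(1.0, rnorm(n, 1.18, 0.06))
  hr_max_obs <- max_hr + rnorm(n, 0, 3)
  rpe_max <- sample(17:20, n, replace = TRUE)
  plateau <- runif(n) < 0.5

  out <- data.frame(
    id = sprintf("S%04d", seq_len(n)), age = age, sex = sex, bmi = bmi,
    pa_score = pa, hrs, stage3_skipped = FALSE,
    rpe_end_stage2 = NA_real_, vo2max_measured = measured,
    rer_max = rer_max, hr_max_observed = hr_max_obs, rpe_max = rpe_max,
    plateau = plateau, true_fitness = fitness, true_max_hr = max_hr,
    true_hr_slope = slope_i, stringsAsFactors = FALSE)
  attr(out, "config") <- config
  out
}

#' Inject a residual structure around a set of estimates
#'
#' Builds a paired cohort in which the "measured" values are the given
#' estimates plus a controlled residual structure:
#' `measured = estimate + b0 + b1 (estimate − mean estimate) + Normal(0,
#' sigma_e)`. With `b0` alone this plants a pure fixed bias (the
#' Bland–Altman fixed bias recovers `-b0`); a nonzero `b1` plants a
#' proportional bias whose sign the Bland–Altman regression must recover.
#' Used to verify that the agreement module detects exactly the structure
#' put in.
#'
#' @param estimates numeric vector of estimated VO2max values.
#' @param b0 fixed offset, mL·kg⁻¹·min⁻¹.
#' @param b1 proportional coefficient (per mL·kg⁻¹·min⁻¹ above the mean
#'   estimate).
#' @param sigma_e residual SD, mL·kg⁻¹·min⁻¹.
#' @param seed optional integer seed.
#' @param id identifiers (defaults to the sequence).
#' @return a [paired_cohort()].
#' @export
#' @examples
#' pc <- inject_residual_structure(c(35, 40, 45), b0 = 2)
#' bland_altman(pc)$fixed_bias  # exactly -2
inject_residual_structure <- function(estimates, b0 = 0, b1 = 0,
                                      sigma_e = 0, seed = NULL,
                                      id = seq_along(estimates)) {
  estimates <- as.numeric(estimates)
  if (anyNA(estimates)) stop("estimates must be complete", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  measured <- estimates + b0 + b1 * (estimates - mean(estimates)) +
    rnorm(length(estimates), 0, sigma_e)
  paired_cohort(id, measured, estimates)
}
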