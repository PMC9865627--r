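#' Coefficients of the multiple regression estimator
#'
#' The published fixed-coefficient equation (units mL·kg⁻¹·min⁻¹ per unit of
#' predictor):
#' \deqn{eVO_{2max} = 64.22 - 0.23\,age + 5.74\,I(male) - 0.57\,BMI
#'   + 0.19\,PA - 0.18\,HRindex}
#' The coefficients travel as a set: override them only as a complete
#' replacement, never piecemeal, so that the equation in use is always
#' well-defined.
#'
#' @param intercept,age,sex,bmi,pa,hr_index the six coefficients.
#' @return named numeric vector of class `"mrm_coefficients"`.
#' @export
mrm_coefficients <- function(intercept = 64.22, age = -0.23, sex = 5.74,
                             bmi = -0.57, pa = 0.19, hr_index = -0.18) {
  structure(c(intercept = intercept, age = age, sex = sex, bmi = bmi,
              pa = pa, hr_index = hr_index),
            class = "mrm_coefficients")
}

#' Stage-constant VO2 values for the linear extrapolation estimator
#'
#' Each step-test stage is assigned a predetermined oxygen-uptake constant
#' (mL·kg⁻¹·min⁻¹) for the ordered stages (rest, exercise 1–3, recovery
#' 1–2): females (4, 13, 19, 22, 17, 8) and males (4, 14, 20, 23, 18, 8).
#' The slightly elevated recovery constants absorb the post-exercise
#' heart-rate elevation relative to steady state, which is why the
#' extrapolation treats all six stages as one line.
#'
#' @param sex sex token; see [normalize_sex()].
#' @return named numeric vector of length 6
#'   (`rest`, `ex1`, `ex2`, `ex3`, `rec1`, `rec2`).
#' @export
#' @examples
#' lem_constants("female")
lem_constants <- function(sex) {
  sex <- normalize_sex(sex)
  vals <- switch(sex,
                 female = c(4, 13, 19, 22, 17, 8),
                 male = c(4, 14, 20, 23, 18, 8))
  setNames(vals, c("rest", "ex1", "ex2", "ex3", "rec1", "rec2"))
}

# internal container for one estimator's output
estimate_result <- function(method, evo2max = NA_real_,
                            reason = NA_character_, hr_index = NA_real_,
                            lem_slope = NA_real_, lem_intercept = NA_real_,
                            predicted_max_hr = NA_real_,
                            switched_to_lem = NA) {
  stopifnot(method %in% c("MRM", "LEM", "combined"))
  if (is.na(evo2max) && is.na(reason))
    stop("a missing estimate must carry a reason code", call. = FALSE)
  structure(
    list(method = method, evo2max = as.numeric(evo2max), reason = reason,
         hr_index = hr_index, lem_slope = lem_slope,
         lem_intercept = lem_intercept, predicted_max_hr = predicted_max_hr,
         switched_to_lem = switched_to_lem),
    class = "estimate_result"
  )
}

#' @export
print.estimate_result <- function(x, ...) {
  if (is.na(x$evo2max)) {
    cat(sprintf("%s estimate: missing (%s)\n", x$method, x$reason))
  } else {
    cat(sprintf("%s estimate: %.2f mL/kg/min\n", x$method, x$evo2max))
    if (!is.na(x$lem_slope))
      cat(sprintf("  extrapolation: HR = %.3f + %.3f x VO2, max HR %.1f\n",
                  x$lem_intercept, x$lem_slope, x$predicted_max_hr))
    if (isTRUE(x$switched_to_lem))
      cat("  (regression estimate reached the cut-off; extrapolation used)\n")
  }
  invisible(x)
}

#' Evaluate the regression equation at raw predictor values
#'
#' The bare linear form behind [estimate_mrm()], vectorized over its
#' arguments, without clipping or validation. Exposed so that the equation
#' can be evaluated on predictor columns directly.
#'
#' @param age years; `sex_male` 0/1 indicator; `bmi` kg·m⁻²; `pa_score`
#'   points; `hr_index` bpm.
#' @param sex_male,bmi,pa_score,hr_index see above.
#' @param coefs an [mrm_coefficients()] set.
#' @return estimated VO2max, mL·kg⁻¹·min⁻¹.
#' @export
#' @examples
#' mrm_evaluate(0, 0, 0, 0, 0)  # intercept: 64.22
mrm_evaluate <- function(age, sex_male, bmi, pa_score, hr_index,
                         coefs = mrm_coefficients()) {
  coefs[["intercept"]] + coefs[["age"]] * age + coefs[["sex"]] * sex_male +
    coefs[["bmi"]] * bmi + coefs[["pa"]] * pa_score +
    coefs[["hr_index"]] * hr_index
}

#' Multiple-regression VO2max estimate
#'
#' Evaluates the fixed-coefficient equation (see [mrm_coefficients()]) for
#' one participant. The heart-rate index can be given directly or computed
#' from a step-test record; when stage 3 was skipped the index — and hence
#' this estimator — is undefined and a missing result with a reason code is
#' returned.
#'
#' @param p a [participant()].
#' @param hr_index heart-rate index in bpm, or `NULL` to compute it from
#'   `record`.
#' @param record a [step_record()] (used when `hr_index` is `NULL`).
#' @param coefs an [mrm_coefficients()] set.
#' @return an `estimate_result` with `method = "MRM"`.
#' @export
#' @examples
#' p <- participant("S1", 48.3, "female", bmi = 21.6, pa_score = 8.6)
#' estimate_mrm(p, hr_index = 46.9)  # 33.991
estimate_mrm <- function(p, hr_index = NULL, record = NULL,
                         coefs = mrm_coefficients()) {
  stopifnot(inherits(p, "participant"))
  if (is.null(hr_index)) {
    if (is.null(record))
      stop("either 'hr_index' or 'record' is required", call. = FALSE)
    hr_index <- hr_index(record)
  }
  if (is.na(hr_index))
    return(estimate_result(
      "MRM", reason = attr(hr_index, "reason") %||%
        "hr_index missing"))
  val <- mrm_evaluate(p$age, as.numeric(p$sex == "male"), p$bmi,
                      p$pa_score, as.numeric(hr_index), coefs)
  estimate_result("MRM", evo2max = val, hr_index = as.numeric(hr_index))
}

#' Least-squares line through the step-test scatter
#'
#' Builds the per-subject scatter of stage heart rate (y, bpm) against the
#' stage-constant VO2 values (x, mL·kg⁻¹·min⁻¹; see [lem_constants()]) and
#' fits the ordinary least-squares line of HR on VO2. When stage 3 was
#' skipped, the five available stages are used and the stage-3 constant is
#' dropped. The regression direction is deliberate — HR on VO2, matching the
#' axes of the extrapolation — and is later inverted algebraically by
#' [estimate_lem()]; regressing VO2 on HR would give a different line
#' whenever the points are not collinear.
#'
#' @param record a [step_record()].
#' @param sex sex token (selects the constants) — ignored when `constants`
#'   is supplied.
#' @param constants stage VO2 constants, ordered as in [lem_constants()].
#' @return a list of class `"lem_fit"`: `slope` (bpm per mL·kg⁻¹·min⁻¹),
#'   `intercept` (bpm), `n_points`, and the fitted `vo2`/`hr` vectors.
#' @export
#' @examples
#' r <- step_record(72, 99, 117, 126, hr_rec1 = 111, hr_rec2 = 84)
#' fit_lem_line(r, "female")  # exactly collinear: slope 3, intercept 60
fit_lem_line <- function(record, sex, constants = lem_constants(sex)) {
  stopifnot(inherits(record, "step_record"), length(constants) == 6L)
  x <- as.numeric(constants)
  y <- c(record$hr_rest, record$hr_ex1, record$hr_ex2, record$hr_ex3,
         record$hr_rec1, record$hr_rec2)
  if (record$stage3_skipped) {
    x <- x[-4L]
    y <- y[-4L]
  }
  keep <- !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L || length(unique(x)) < 2L)
    stop("need at least 2 stages with distinct VO2 constants to fit a line",
         call. = FALSE)
  xc <- x - mean(x)
  slope <- sum(xc * y) / sum(xc * xc)
  intercept <- mean(y) - slope * mean(x)
  structure(list(slope = slope, intercept = intercept,
                 n_points = length(x), vo2 = x, hr = y),
            class = "lem_fit")
}

#' Linear-extrapolation VO2max estimate
#'
#' Extrapolates the per-subject least-squares line from [fit_lem_line()] up
#' to the age-predicted maximal heart rate (tanaka formula 208 − 0.7·age by
#' default) and reads off the corresponding VO2:
#' \deqn{eVO_{2max} = (HR_{max,pred} - intercept) / slope}
#' Near-flat or inverted heart-rate responses make the extrapolation
#' meaningless, so slopes at or below `slope_min` (default 0.1 bpm per
#' mL·kg⁻¹·min⁻¹) yield a missing result with a reason code, as does a
#' non-positive extrapolated value. Estimates are reported raw, without
#' truncation or winsorization.
#'
#' @param p a [participant()].
#' @param record a [step_record()].
#' @param constants stage VO2 constants (default chosen by the
#'   participant's sex).
#' @param formula maximal-heart-rate formula, `"tanaka"` (default) or
#'   `"fox"`.
#' @param slope_min minimal admissible slope, bpm per mL·kg⁻¹·min⁻¹.
#' @return an `estimate_result` with `method = "LEM"` carrying the fitted
#'   slope, intercept and predicted maximal heart rate.
#' @export
#' @examples
#' p <- participant("S1", 40, "female", bmi = 22, pa_score = 10)
#' r <- step_record(72, 99, 117, 126, hr_rec1 = 111, hr_rec2 = 84)
#' estimate_lem(p, r)  # (180 - 60) / 3 = 40
estimate_lem <- function(p, record, constants = lem_constants(p$sex),
                         formula = c("tanaka", "fox"), slope_min = 0.1) {
  stopifnot(inherits(p, "participant"))
  formula <- match.arg(formula)
  fit <- fit_lem_line(record, p$sex, constants)
  mhr <- predicted_max_hr(p$age, formula)
  if (!is.finite(fit$slope) || fit$slope <= slope_min)
    return(estimate_result(
      "LEM", reason = "non-positive or degenerate slope",
      lem_slope = fit$slope, lem_intercept = fit$intercept,
      predicted_max_hr = mhr))
  val <- (mhr - fit$intercept) / fit$slope
  if (val <= 0)
    return(estimate_result(
      "LEM", reason = "extrapolated VO2max non-positive",
      lem_slope = fit$slope, lem_intercept = fit$intercept,
      predicted_max_hr = mhr))
  estimate_result("LEM", evo2max = val, lem_slope = fit$slope,
                  lem_intercept = fit$intercept, predicted_max_hr = mhr)
}

#' Combined VO2max estimate
#'
#' The regression estimator is accurate for average fitness but compresses
#' high values (proportional bias), while the extrapolation estimator is
#' noisier but unbiased at the top of the range. The combined rule therefore
#' (1) computes the regression estimate and (2) recomputes it by linear
#' extrapolation when it reaches the cut-off (default 45.0 mL·kg⁻¹·min⁻¹).
#' The returned value is always exactly one leg's value — no averaging. By
#' default the comparison is inclusive (`>= cutoff`); set `cutoff_strict`
#' for strict `>`. If the extrapolation leg fails after switching, the
#' result is missing with a reason — it does not silently fall back to the
#' regression value.
#'
#' @param p a [participant()].
#' @param record a [step_record()].
#' @param cutoff switch threshold, mL·kg⁻¹·min⁻¹.
#' @param cutoff_strict logical; use strict `>` instead of `>=`.
#' @param coefs an [mrm_coefficients()] set.
#' @param constants stage VO2 constants for the extrapolation leg.
#' @param formula maximal-heart-rate formula for the extrapolation leg.
#' @param slope_min minimal admissible extrapolation slope.
#' @return an `estimate_result` with `method = "combined"` and
#'   `switched_to_lem` set.
#' @export
estimate_combined <- function(p, record, cutoff = 45,
                              cutoff_strict = FALSE,
                              coefs = mrm_coefficients(),
                              constants = lem_constants(p$sex),
                              formula = c("tanaka", "fox"),
                              slope_min = 0.1) {
  stopifnot(cutoff > 0 || is.infinite(cutoff))
  mrm <- estimate_mrm(p, record = record, coefs = coefs)
  if (is.na(mrm$evo2max)) {
    res <- mrm
    res$method <- "combined"
    res$reason <- paste0("MRM leg: ", mrm$reason)
    res$switched_to_lem <- NA
    return(res)
  }
  switch_leg <- if (cutoff_strict) mrm$evo2max > cutoff else
    mrm$evo2max >= cutoff
  if (switch_leg) {
    lem <- estimate_lem(p, record, constants = constants,
                        formula = formula, slope_min = slope_min)
    res <- lem
    res$method <- "combined"
    res$hr_index <- mrm$hr_index
    res$switched_to_lem <- TRUE
    if (is.na(lem$evo2max))
      res$reason <- paste0("LEM leg after switch: ", lem$reason)
    return(res)
  }
  res <- mrm
  res$method <- "combined"
  res$switched_to_lem <- FALSE
  res
}
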