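#' Construct and validate a participant record
#'
#' A participant carries the demographic and anthropometric predictors of the
#' regression estimator: age, sex, body mass index (BMI), and the
#' physical-activity (PA) questionnaire score. BMI is weight in kilograms
#' divided by the square of height in meters; it is derived from
#' `height`/`weight` when not supplied directly. Supplying all three requires
#' them to be consistent (within 1e-9), otherwise validation fails.
#'
#' The estimating equations were validated on adults aged 30–60. Ages outside
#' that window are accepted (the equations are formally evaluable at any
#' adult age) but the returned object carries
#' `"age_outside_validated_range"` in its `flags` field rather than raising a
#' warning, so that bulk simulation stays quiet.
#'
#' @param id participant identifier (coerced to character).
#' @param age age in years, > 0.
#' @param sex sex token; see [normalize_sex()].
#' @param height standing height in cm (optional if `bmi` given).
#' @param weight body weight in kg (optional if `bmi` given).
#' @param bmi body mass index in kg·m⁻² (optional if `height` and `weight`
#'   given).
#' @param pa_score physical-activity questionnaire score, 0–44 points.
#' @return an object of class `"participant"`: a list with fields `id`,
#'   `age`, `sex`, `height`, `weight`, `bmi`, `pa_score`, `flags`.
#' @export
#' @examples
#' participant("S01", age = 48.3, sex = "female",
#'             height = 158.6, weight = 54.4, pa_score = 8.6)
participant <- function(id, age, sex, height = NULL, weight = NULL,
                        bmi = NULL, pa_score) {
  age <- check_num(age, "age")
  if (age <= 0) stop("'age' must be positive", call. = FALSE)
  sex <- normalize_sex(sex)
  if (length(sex) != 1L) stop("'sex' must be a single value", call. = FALSE)
  pa_score <- check_num(pa_score, "pa_score", lower = 0, upper = 44)

  has_hw <- !is.null(height) && !is.null(weight) &&
    !is.na(height) && !is.na(weight)
  if (has_hw) {
    height <- check_num(height, "height", lower = 50, upper = 250)
    weight <- check_num(weight, "weight", lower = 10, upper = 400)
    derived <- weight / (height / 100)^2
    if (!is.null(bmi) && !is.na(bmi) &&
        abs(as.numeric(bmi) - derived) > 1e-9)
      stop(sprintf("'bmi' (%s) inconsistent with height/weight (derived %s)",
                   format(bmi), format(derived)), call. = FALSE)
    bmi <- derived
  } else {
    height <- NA_real_
    weight <- NA_real_
    if (is.null(bmi) || is.na(bmi))
      stop("either 'bmi' or both 'height' and 'weight' are required",
           call. = FALSE)
    bmi <- check_num(bmi, "bmi", lower = 5, upper = 100)
  }

  flags <- character(0)
  if (age < 30 || age > 60) flags <- c(flags, "age_outside_validated_range")

  structure(
    list(id = as.character(id), age = age, sex = sex,
         height = height, weight = weight, bmi = bmi,
         pa_score = pa_score, flags = flags),
    class = "participant"
  )
}

#' @export
print.participant <- function(x, ...) {
  cat(sprintf("Participant %s: %s, %.1f y, BMI %.1f, PA score %.1f\n",
              x$id, x$sex, x$age, x$bmi, x$pa_score))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Construct a step-test record
#'
#' Heart rates (bpm) at the six stages of the step test: seated rest, three
#' 1-minute exercise stages, and two 1-minute recovery stages. The protocol
#' allows skipping exercise stage 3 when stage 2 already brought the
#' participant near maximal effort (see [check_stage3_skip()]); a skipped
#' record must not carry `hr_ex3`, and the heart-rate index is then
#' undefined.
#'
#' All present heart rates must lie in \[30, 230\] bpm — a deliberately
#' generous physiological envelope whose purpose is to reject unit mistakes
#' (e.g. RR intervals in ms) without excluding athletes.
#'
#' @param hr_rest,hr_ex1,hr_ex2,hr_ex3,hr_rec1,hr_rec2 stage heart rates in
#'   bpm; `hr_ex3` must be omitted (or `NA`) iff `stage3_skipped` is `TRUE`.
#' @param stage3_skipped logical; was exercise stage 3 skipped?
#' @param rpe_end_stage2 optional Borg 6–20 rating of perceived exertion at
#'   the end of stage 2 (needed to evaluate the skip rule).
#' @return an object of class `"step_record"`.
#' @export
#' @examples
#' step_record(hr_rest = 72, hr_ex1 = 99, hr_ex2 = 117, hr_ex3 = 126,
#'             hr_rec1 = 111, hr_rec2 = 84)
step_record <- function(hr_rest, hr_ex1, hr_ex2, hr_ex3 = NULL,
                        hr_rec1, hr_rec2, stage3_skipped = FALSE,
                        rpe_end_stage2 = NULL) {
  stage3_skipped <- isTRUE(stage3_skipped)
  hr_rest <- check_num(hr_rest, "hr_rest", 30, 230)
  hr_ex1  <- check_num(hr_ex1, "hr_ex1", 30, 230)
  hr_ex2  <- check_num(hr_ex2, "hr_ex2", 30, 230)
  hr_rec1 <- check_num(hr_rec1, "hr_rec1", 30, 230)
  hr_rec2 <- check_num(hr_rec2, "hr_rec2", 30, 230)
  if (stage3_skipped) {
    if (!is.null(hr_ex3) && !all(is.na(hr_ex3)))
      stop("'hr_ex3' must be absent when stage 3 was skipped", call. = FALSE)
    hr_ex3 <- NA_real_
  } else {
    if (is.null(hr_ex3) || all(is.na(hr_ex3)))
      stop("'hr_ex3' is required unless stage3_skipped is TRUE",
           call. = FALSE)
    hr_ex3 <- check_num(hr_ex3, "hr_ex3", 30, 230)
  }
  if (!is.null(rpe_end_stage2) && !is.na(rpe_end_stage2))
    rpe_end_stage2 <- check_num(rpe_end_stage2, "rpe_end_stage2", 6, 20)
  else
    rpe_end_stage2 <- NA_real_

  structure(
    list(hr_rest = hr_rest, hr_ex1 = hr_ex1, hr_ex2 = hr_ex2,
         hr_ex3 = hr_ex3, hr_rec1 = hr_rec1, hr_rec2 = hr_rec2,
         stage3_skipped = stage3_skipped, rpe_end_stage2 = rpe_end_stage2),
    class = "step_record"
  )
}

#' @export
print.step_record <- function(x, ...) {
  cat(sprintf(
    "Step test HRs (bpm): rest %.0f | ex %.0f %.0f %s | rec %.0f %.0f%s\n",
    x$hr_rest, x$hr_ex1, x$hr_ex2,
    if (x$stage3_skipped) "(skipped)" else sprintf("%.0f", x$hr_ex3),
    x$hr_rec1, x$hr_rec2,
    if (is.na(x$rpe_end_stage2)) "" else
      sprintf(" | RPE end-2 %.0f", x$rpe_end_stage2)))
  invisible(x)
}

#' Construct a maximal treadmill-test record
#'
#' Outcome of the graded maximal treadmill test used to measure VO2max
#' directly: the highest 30-second average VO2, the maximal respiratory
#' exchange ratio (RER), the observed maximal heart rate, the final Borg
#' rating, and whether a VO2 plateau was observed. Whether the measurement
#' counts as a true maximum is decided by [verify_max_effort()].
#'
#' @param vo2_peak_30s highest 30-s average VO2, mL·kg⁻¹·min⁻¹ (> 0).
#' @param rer_max maximal respiratory exchange ratio (> 0).
#' @param hr_max_observed observed maximal heart rate, bpm.
#' @param rpe_max final Borg 6–20 rating.
#' @param plateau logical; did VO2 plateau despite increasing workload?
#'   Unknown is treated as `FALSE` (criterion unmet).
#' @return an object of class `"treadmill_record"`.
#' @export
treadmill_record <- function(vo2_peak_30s, rer_max, hr_max_observed,
                             rpe_max, plateau = FALSE) {
  vo2_peak_30s <- check_num(vo2_peak_30s, "vo2_peak_30s")
  if (vo2_peak_30s <= 0) stop("'vo2_peak_30s' must be positive", call. = FALSE)
  rer_max <- check_num(rer_max, "rer_max")
  if (rer_max <= 0) stop("'rer_max' must be positive", call. = FALSE)
  hr_max_observed <- check_num(hr_max_observed, "hr_max_observed", 30, 250)
  rpe_max <- check_num(rpe_max, "rpe_max", 6, 20)
  structure(
    list(vo2_peak_30s = vo2_peak_30s, rer_max = rer_max,
         hr_max_observed = hr_max_observed, rpe_max = rpe_max,
         plateau = isTRUE(plateau)),
    class = "treadmill_record"
  )
}
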