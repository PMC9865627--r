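#' Step-test heart-rate index
#'
#' The heart-rate index summarizes the chronotropic response to the step
#' test:
#' \deqn{(HR_{ex3} - HR_{ex1}) + (HR_{rec1} - HR_{rec2})}
#' Fit individuals show a smaller exercise-stage rise and a faster recovery
#' drop, so lower values indicate higher fitness. The index may be negative
#' (a recovery rebound larger than the exercise rise). When exercise stage 3
#' was skipped the index is undefined: `NA` is returned with a `"reason"`
#' attribute.
#'
#' @param record a [step_record()].
#' @return the index in bpm, or `NA` (with attribute `reason`) when stage 3
#'   was skipped.
#' @export
#' @examples
#' r <- step_record(70, 100, 125, 150, hr_rec1 = 120, hr_rec2 = 100)
#' hr_index(r)  # (150 - 100) + (120 - 100) = 70
hr_index <- function(record) {
  stopifnot(inherits(record, "step_record"))
  if (record$stage3_skipped)
    return(structure(NA_real_,
                     reason = "hr_index undefined when stage 3 skipped"))
  (record$hr_ex3 - record$hr_ex1) + (record$hr_rec1 - record$hr_rec2)
}

#' Age-predicted maximal heart rate
#'
#' Two conventional formulas are supported: the classical `"fox"` formula
#' 220 − age, and the `"tanaka"` formula 208 − 0.7·age. They agree at age 40
#' (both 180 bpm); above 40 the tanaka prediction is the higher of the two.
#' In this package the fox formula feeds the stage-3 skip rule and
#' maximal-effort verification, while the tanaka formula anchors the linear
#' extrapolation estimator — each use-site accepts a `formula` argument.
#'
#' @param age age in years (vectorized, all > 0).
#' @param formula `"tanaka"` (default) or `"fox"`.
#' @return predicted maximal heart rate(s) in bpm.
#' @export
#' @examples
#' predicted_max_hr(40, "fox")      # 180
#' predicted_max_hr(48.3, "tanaka") # 174.19
predicted_max_hr <- function(age, formula = c("tanaka", "fox")) {
  formula <- match.arg(formula)
  if (any(!is.finite(age)) || any(age <= 0))
    stop("'age' must be positive and finite", call. = FALSE)
  switch(formula,
         fox = 220 - age,
         tanaka = 208 - 0.7 * age)
}

#' Stage-3 skip rule
#'
#' The protocol lets a participant skip the third exercise stage when both
#' end-of-stage-2 criteria are met: heart rate at or above 80% of the
#' age-predicted maximum (fox formula, 220 − age) and a Borg rating of
#' perceived exertion at or above 17. Both thresholds are read as "at
#' least", since they are stated as targets. A missing RPE makes the rule
#' unverifiable: `FALSE` is returned with a warning.
#'
#' @param hr_end_stage2 heart rate at the end of exercise stage 2, bpm.
#' @param rpe_end_stage2 Borg 6–20 rating at the end of stage 2 (may be
#'   `NA`).
#' @param age age in years.
#' @return `TRUE` iff both criteria are met.
#' @export
#' @examples
#' check_stage3_skip(150, 18, 40)  # 0.8 * 180 = 144; TRUE
check_stage3_skip <- function(hr_end_stage2, rpe_end_stage2, age) {
  hr_end_stage2 <- check_num(hr_end_stage2, "hr_end_stage2", 30, 230)
  if (is.null(rpe_end_stage2) || is.na(rpe_end_stage2)) {
    warning("RPE at end of stage 2 missing; skip criteria cannot be ",
            "established, returning FALSE", call. = FALSE)
    return(FALSE)
  }
  rpe_end_stage2 <- check_num(rpe_end_stage2, "rpe_end_stage2", 6, 20)
  hr_end_stage2 >= 0.8 * predicted_max_hr(age, "fox") &&
    rpe_end_stage2 >= 17
}

#' Thresholds for maximal-effort verification
#'
#' @param rer_threshold respiratory exchange ratio the test must exceed
#'   (strict `>`; default 1.10).
#' @param hr_window maximal allowed distance of the observed maximal heart
#'   rate from the fox age-predicted maximum, bpm (default 10).
#' @param rpe_threshold Borg rating the final RPE must exceed (strict `>`;
#'   default 17). Note the asymmetry with [check_stage3_skip()], where the
#'   threshold of 17 is inclusive: the effort criterion is stated as
#'   "exceeded".
#' @param min_criteria_met how many of the four criteria must hold
#'   (default 3).
#' @return a list of class `"effort_criteria"`.
#' @export
effort_criteria <- function(rer_threshold = 1.10, hr_window = 10,
                            rpe_threshold = 17, min_criteria_met = 3) {
  stopifnot(rer_threshold > 0, hr_window > 0, rpe_threshold > 0,
            min_criteria_met >= 1, min_criteria_met <= 4)
  structure(list(rer_threshold = rer_threshold, hr_window = hr_window,
                 rpe_threshold = rpe_threshold,
                 min_criteria_met = min_criteria_met),
            class = "effort_criteria")
}

#' Verify that a treadmill test reached a true maximum
#'
#' A measured VO2 peak counts as VO2max when at least `min_criteria_met`
#' (default 3) of four criteria hold: (i) RER exceeded 1.10; (ii) the
#' observed maximal heart rate was within 10 bpm of the fox age-predicted
#' maximum (220 − age); (iii) the final RPE exceeded 17; (iv) VO2 reached a
#' plateau despite increasing workload. The plateau is taken as a reported
#' boolean (unknown counts as unmet); see [vo2_plateau()] for an optional
#' helper.
#'
#' @param treadmill a [treadmill_record()].
#' @param age age in years.
#' @param criteria an [effort_criteria()] object.
#' @return a list with `met` (logical) and `criteria`, a named logical
#'   vector (`rer`, `hr`, `rpe`, `plateau`).
#' @export
#' @examples
#' t <- treadmill_record(51, rer_max = 1.15, hr_max_observed = 178,
#'                       rpe_max = 19, plateau = FALSE)
#' verify_max_effort(t, age = 45)
verify_max_effort <- function(treadmill, age, criteria = effort_criteria()) {
  stopifnot(inherits(treadmill, "treadmill_record"),
            inherits(criteria, "effort_criteria"))
  crit <- c(
    rer = treadmill$rer_max > criteria$rer_threshold,
    hr = abs(treadmill$hr_max_observed - predicted_max_hr(age, "fox")) <=
      criteria$hr_window,
    rpe = treadmill$rpe_max > criteria$rpe_threshold,
    plateau = isTRUE(treadmill$plateau)
  )
  list(met = sum(crit) >= criteria$min_criteria_met, criteria = crit)
}

#' VO2 plateau helper
#'
#' Optional convenience for deciding the plateau criterion from the final
#' two stage-averaged VO2 values: a plateau is declared when the last
#' increment falls below `delta` (default 2.0 mL·kg⁻¹·min⁻¹). This helper is
#' never invoked automatically — [verify_max_effort()] takes the plateau as
#' a reported flag, because plateau operationalizations vary across
#' laboratories.
#'
#' @param vo2_final,vo2_previous stage-averaged VO2 at the last two
#'   workloads, mL·kg⁻¹·min⁻¹.
#' @param delta increment threshold, mL·kg⁻¹·min⁻¹.
#' @return logical.
#' @export
vo2_plateau <- function(vo2_final, vo2_previous, delta = 2.0) {
  (vo2_final - vo2_previous) < delta
}
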