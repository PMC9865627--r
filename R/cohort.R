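#' Run the estimators over a cohort table
#'
#' Applies the requested estimators row by row to a cohort data.frame in
#' the cohort file schema (see [read_cohort()] / [generate_cohort()]).
#' Rows that fail validation, or whose estimator legs are undefined (e.g.
#' the regression estimator after a stage-3 skip), yield `NA` estimates
#' with a reason code in the matching `reason_*` column; rows are never
#' dropped, so outputs stay join-aligned with inputs.
#'
#' @param cohort a data.frame with at least `id`, `age`, `sex`, `pa_score`,
#'   the six stage heart-rate columns, and `bmi` or `height_cm` +
#'   `weight_kg`.
#' @param methods subset of `c("mrm", "lem", "combined")`.
#' @param coefs an [mrm_coefficients()] set.
#' @param cutoff,cutoff_strict combined-rule switch threshold and
#'   comparison; see [estimate_combined()].
#' @param max_hr_formula formula for the extrapolation anchor.
#' @param slope_min minimal admissible extrapolation slope.
#' @return a data.frame with `id`, per-method `evo2max_*` and `reason_*`
#'   columns, and the intermediates `hr_index`, `lem_slope`,
#'   `lem_intercept`, `predicted_max_hr`, `switched_to_lem`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n = 5, seed = 1))
#' estimate_cohort(coh)
estimate_cohort <- function(cohort,
                            methods = c("mrm", "lem", "combined"),
                            coefs = mrm_coefficients(), cutoff = 45,
                            cutoff_strict = FALSE,
                            max_hr_formula = c("tanaka", "fox"),
                            slope_min = 0.1) {
  stopifnot(is.data.frame(cohort))
  methods <- match.arg(methods, several.ok = TRUE)
  max_hr_formula <- match.arg(max_hr_formula)
  n <- nrow(cohort)

  col <- function(name) if (name %in% names(cohort)) cohort[[name]] else
    rep(NA_real_, n)
  na_col <- rep(NA_real_, n)
  out <- data.frame(id = as.character(col("id")),
                    stringsAsFactors = FALSE)
  for (m in methods) {
    out[[paste0("evo2max_", m)]] <- na_col
    out[[paste0("reason_", m)]] <- NA_character_
  }
  out$hr_index <- na_col
  out$lem_slope <- na_col
  out$lem_intercept <- na_col
  out$predicted_max_hr <- na_col
  out$switched_to_lem <- NA

  skipped <- col("stage3_skipped")
  skipped <- !is.na(skipped) & (skipped == TRUE | skipped == "TRUE" |
                                  skipped == 1)
  for (i in seq_len(n)) {
    row_err <- NULL
    p <- tryCatch(
      participant(id = col("id")[i], age = col("age")[i],
                  sex = cohort$sex[i],
                  height = col("height_cm")[i],
                  weight = col("weight_kg")[i],
                  bmi = col("bmi")[i], pa_score = col("pa_score")[i]),
      error = function(e) { row_err <<- conditionMessage(e); NULL })
    rec <- if (is.null(row_err)) tryCatch(
      step_record(hr_rest = col("hr_rest")[i], hr_ex1 = col("hr_ex1")[i],
                  hr_ex2 = col("hr_ex2")[i],
                  hr_ex3 = col("hr_ex3")[i],
                  hr_rec1 = col("hr_rec1")[i],
                  hr_rec2 = col("hr_rec2")[i],
                  stage3_skipped = skipped[i],
                  rpe_end_stage2 = col("rpe_end_stage2")[i]),
      error = function(e) { row_err <<- conditionMessage(e); NULL })
    if (!is.null(row_err)) {
      for (m in methods)
        out[[paste0("reason_", m)]][i] <- paste0("invalid row: ", row_err)
      next
    }
    hri <- hr_index(rec)
    out$hr_index[i] <- as.numeric(hri)
    if ("mrm" %in% methods) {
      res <- estimate_mrm(p, record = rec, coefs = coefs)
      out$evo2max_mrm[i] <- res$evo2max
      out$reason_mrm[i] <- res$reason
    }
    if ("lem" %in% methods) {
      res <- estimate_lem(p, rec, formula = max_hr_formula,
                          slope_min = slope_min)
      out$evo2max_lem[i] <- res$evo2max
      out$reason_lem[i] <- res$reason
      out$lem_slope[i] <- res$lem_slope
      out$lem_intercept[i] <- res$lem_intercept
      out$predicted_max_hr[i] <- res$predicted_max_hr
    }
    if ("combined" %in% methods) {
      res <- estimate_combined(p, rec, cutoff = cutoff,
                               cutoff_strict = cutoff_strict,
                               coefs = coefs, formula = max_hr_formula,
                               slope_min = slope_min)
      out$evo2max_combined[i] <- res$evo2max
      out$reason_combined[i] <- res$reason
      out$switched_to_lem[i] <- res$switched_to_lem
      if (!("lem" %in% methods) && !is.na(res$lem_slope)) {
        out$lem_slope[i] <- res$lem_slope
        out$lem_intercept[i] <- res$lem_intercept
        out$predicted_max_hr[i] <- res$predicted_max_hr
      }
    }
  }
  n_missing <- sum(is.na(out[[paste0("evo2max_", methods[1])]]))
  attr(out, "n_missing_first_method") <- n_missing
  out
}
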