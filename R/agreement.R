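#' Paired measured/estimated VO2max values
#'
#' A validated container for method-comparison statistics: one row per
#' participant, with the treadmill-measured VO2max and one estimator's
#' value, no missing entries, unique ids.
#'
#' @param id participant identifiers (unique).
#' @param measured treadmill-measured VO2max, mL·kg⁻¹·min⁻¹.
#' @param estimated estimated VO2max, mL·kg⁻¹·min⁻¹.
#' @return a `data.frame` of class `"paired_cohort"`.
#' @export
paired_cohort <- function(id, measured, estimated) {
  id <- as.character(id)
  measured <- as.numeric(measured)
  estimated <- as.numeric(estimated)
  n <- length(id)
  if (length(measured) != n || length(estimated) != n)
    stop("'id', 'measured' and 'estimated' must have equal length",
         call. = FALSE)
  if (anyNA(measured) || anyNA(estimated))
    stop("paired cohorts must not contain missing values", call. = FALSE)
  if (anyDuplicated(id))
    stop("duplicate ids in paired cohort", call. = FALSE)
  structure(data.frame(id = id, measured = measured, estimated = estimated,
                       stringsAsFactors = FALSE),
            class = c("paired_cohort", "data.frame"))
}

# two-tailed one-sample t-test p-value, NA when the data are (numerically)
# constant rather than an error
safe_t_p <- function(d) {
  if (sd(d) == 0) return(NA_real_)
  tryCatch(t.test(d)$p.value, error = function(e) NA_real_)
}

# accept a paired_cohort / data.frame in place of (measured, estimated)
as_pairs <- function(measured, estimated = NULL) {
  if (is.data.frame(measured)) {
    stopifnot(all(c("measured", "estimated") %in% names(measured)))
    list(m = as.numeric(measured$measured),
         e = as.numeric(measured$estimated))
  } else {
    if (is.null(estimated))
      stop("'estimated' is required when 'measured' is a vector",
           call. = FALSE)
    if (length(measured) != length(estimated))
      stop("'measured' and 'estimated' must have equal length",
           call. = FALSE)
    list(m = as.numeric(measured), e = as.numeric(estimated))
  }
}

#' Constant error of an estimator
#'
#' The constant error is the mean signed difference between measured and
#' estimated values, CE = mean(measured − estimated): positive CE means the
#' estimator runs low on average. Returned with the sample standard
#' deviation of the differences and a two-tailed one-sample t-test of the
#' differences against zero (`NA` when the differences are constant).
#'
#' Note the sign convention: CE uses measured − estimated, whereas the
#' Bland–Altman fixed bias ([bland_altman()]) uses estimated − measured, so
#' `fixed_bias == -ce` exactly. Both conventions are standard in their
#' respective literatures and are kept side by side deliberately.
#'
#' @param measured,estimated numeric vectors, or a [paired_cohort()] as the
#'   first argument.
#' @return list with `n`, `ce`, `ce_sd`, `ce_p`.
#' @export
#' @examples
#' constant_error(c(38, 40, 42), c(37, 41, 40))  # ce = 2/3
constant_error <- function(measured, estimated = NULL) {
  p <- as_pairs(measured, estimated)
  n <- length(p$m)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  d <- p$m - p$e
  list(n = n, ce = mean(d), ce_sd = sd(d), ce_p = safe_t_p(d))
}

#' Standard error of the estimate
#'
#' SEE = SD(measured) × sqrt(1 − r²), where r is the Pearson correlation of
#' measured with estimated and the SD is the sample (n − 1) standard
#' deviation. The SEE reflects scatter about the regression line only; it is
#' blind to calibration, being invariant to any positive affine transform of
#' the estimates (contrast [total_error()]).
#'
#' @inheritParams constant_error
#' @return the SEE in mL·kg⁻¹·min⁻¹.
#' @export
standard_error_of_estimate <- function(measured, estimated = NULL) {
  p <- as_pairs(measured, estimated)
  if (length(p$m) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (sd(p$m) == 0 || sd(p$e) == 0)
    stop("zero variance: SEE undefined", call. = FALSE)
  r <- cor(p$m, p$e)
  sd(p$m) * sqrt(max(0, 1 - r^2))
}

#' Total error of an estimator
#'
#' TE = sqrt(mean((measured − estimated)²)): the root-mean-square difference
#' between estimated and measured values. Unlike the SEE it charges both
#' miscalibration and scatter, so TE ≥ SEE and TE ≥ |CE| always; similar SEE
#' and TE indicate that the regression line sits close to the line of
#' identity. The root is part of the definition — it keeps TE in
#' mL·kg⁻¹·min⁻¹, directly comparable to the SEE (this is the conventional
#' RMSE form of cross-validation total error).
#'
#' @inheritParams constant_error
#' @return the TE in mL·kg⁻¹·min⁻¹.
#' @export
#' @examples
#' total_error(c(38, 40, 42), c(37, 41, 40))  # sqrt(2)
total_error <- function(measured, estimated = NULL) {
  p <- as_pairs(measured, estimated)
  if (length(p$m) < 1) stop("need at least 1 pair", call. = FALSE)
  sqrt(mean((p$m - p$e)^2))
}

#' Bland–Altman analysis of a paired cohort
#'
#' Computes the Bland–Altman difference d = estimated − measured per pair
#' and reports the fixed bias (mean of d) with 95% limits of agreement
#' (fixed bias ± 1.96 × sample SD of d — the conventional normal-quantile
#' multiplier, not a t quantile) and a two-tailed one-sample t-test of d
#' against zero. Proportional bias is the Pearson correlation of d with the
#' pair mean (measured + estimated)/2 — the standard Bland–Altman abscissa —
#' with its correlation-test p-value (identical to the regression slope's t
#' test in simple regression). A negative proportional-bias r means the
#' estimator increasingly underestimates at higher values.
#'
#' When the differences or the pair means are constant the proportional
#' bias is undefined; `prop_bias_r` is then `NA` and `prop_reason` says why.
#'
#' @inheritParams constant_error
#' @return list with `n`, `fixed_bias`, `fixed_sd`, `loa_low`, `loa_high`,
#'   `fixed_p`, `prop_bias_r`, `prop_bias_p`, `prop_reason`.
#' @export
#' @examples
#' bland_altman(c(38, 40, 42), c(40, 42, 44))  # constant offset +2
bland_altman <- function(measured, estimated = NULL) {
  p <- as_pairs(measured, estimated)
  n <- length(p$m)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  d <- p$e - p$m
  a <- (p$m + p$e) / 2
  fixed_bias <- mean(d)
  fixed_sd <- sd(d)
  fixed_p <- safe_t_p(d)
  # numerically constant counts as constant (guards exact-offset inputs
  # whose differences only vary by floating-point rounding)
  d_const <- fixed_sd <= 1e-12 * max(1, abs(fixed_bias))
  if (d_const || sd(a) == 0) {
    prop_r <- NA_real_
    prop_p <- NA_real_
    prop_reason <- if (d_const)
      "differences are constant" else "pair means are constant"
  } else {
    ct <- cor.test(d, a)
    prop_r <- unname(ct$estimate)
    prop_p <- ct$p.value
    prop_reason <- NA_character_
  }
  list(n = n, fixed_bias = fixed_bias, fixed_sd = fixed_sd,
       loa_low = fixed_bias - 1.96 * fixed_sd,
       loa_high = fixed_bias + 1.96 * fixed_sd,
       fixed_p = fixed_p, prop_bias_r = prop_r, prop_bias_p = prop_p,
       prop_reason = prop_reason)
}

#' Full agreement report for one estimator
#'
#' Bundles every method-comparison statistic for one estimator against the
#' measured values: constant error with its t-test, SEE, TE, Pearson
#' correlation, and the Bland–Altman fixed/proportional bias with 95%
#' limits of agreement. The two sign conventions coexist:
#' `ce = mean(measured − estimated)` and
#' `fixed_bias = mean(estimated − measured) = -ce`.
#'
#' @inheritParams constant_error
#' @param method label for the estimator (e.g. `"MRM"`).
#' @return a list of class `"agreement_report"`.
#' @export
agreement_report <- function(measured, estimated = NULL, method = "") {
  p <- as_pairs(measured, estimated)
  ce <- constant_error(p$m, p$e)
  ba <- bland_altman(p$m, p$e)
  structure(
    list(method = method, n = ce$n,
         measured_mean = mean(p$m), measured_sd = sd(p$m),
         estimated_mean = mean(p$e), estimated_sd = sd(p$e),
         ce = ce$ce, ce_sd = ce$ce_sd, ce_p = ce$ce_p,
         see = standard_error_of_estimate(p$m, p$e),
         te = total_error(p$m, p$e),
         pearson_r = cor(p$m, p$e),
         fixed_bias = ba$fixed_bias, fixed_sd = ba$fixed_sd,
         loa_low = ba$loa_low, loa_high = ba$loa_high,
         fixed_p = ba$fixed_p,
         prop_bias_r = ba$prop_bias_r, prop_bias_p = ba$prop_bias_p,
         prop_reason = ba$prop_reason),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, digits = 2, ...) {
  cat(sprintf("Agreement report%s (n = %d)\n",
              if (nzchar(x$method)) paste0(": ", x$method) else "", x$n))
  cat(sprintf("  measured  %5.*f +/- %.*f   estimated %5.*f +/- %.*f\n",
              digits, x$measured_mean, digits, x$measured_sd,
              digits, x$estimated_mean, digits, x$estimated_sd))
  cat(sprintf("  CE %.*f +/- %.*f (p = %.2f)   SEE %.*f   TE %.*f   r %.*f\n",
              digits, x$ce, digits, x$ce_sd, x$ce_p,
              digits, x$see, digits, x$te, digits, x$pearson_r))
  cat(sprintf("  Bland-Altman bias %.*f [LoA %.*f, %.*f]",
              digits, x$fixed_bias, digits, x$loa_low, digits, x$loa_high))
  if (is.na(x$prop_bias_r))
    cat(sprintf("   proportional bias undefined (%s)\n", x$prop_reason))
  else
    cat(sprintf("   proportional r = %.*f (p = %.2f)\n",
                digits, x$prop_bias_r, x$prop_bias_p))
  invisible(x)
}

#' Compare several estimators against the measured values
#'
#' Builds one [agreement_report()] per estimate column. Rows with a missing
#' measured value are dropped; within each method, rows with a missing
#' estimate are excluded pairwise (never imputed) and the dropped count is
#' reported. Methods with fewer than 3 complete pairs are skipped with a
#' warning.
#'
#' @param data a data.frame.
#' @param measured name of the measured-VO2max column.
#' @param estimates named character vector: method label -> column name.
#'   Unnamed entries use the column name as label.
#' @return a list of class `"method_comparison"`: `reports` (one per
#'   method), `dropped` (named integer vector), `n_input`.
#' @export
compare_methods <- function(data, measured = "measured",
                            estimates = setdiff(names(data),
                                                c("id", measured))) {
  stopifnot(is.data.frame(data), measured %in% names(data))
  if (is.null(names(estimates))) names(estimates) <- estimates
  unnamed <- !nzchar(names(estimates))
  names(estimates)[unnamed] <- estimates[unnamed]
  missing_cols <- setdiff(estimates, names(data))
  if (length(missing_cols))
    stop("estimate column(s) not found: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  m_all <- as.numeric(data[[measured]])
  reports <- list()
  dropped <- integer(0)
  for (lbl in names(estimates)) {
    e_all <- as.numeric(data[[estimates[[lbl]]]])
    keep <- !is.na(m_all) & !is.na(e_all)
    dropped[lbl] <- sum(!keep)
    if (sum(keep) < 3) {
      warning(sprintf("method '%s': only %d complete pairs, skipped",
                      lbl, sum(keep)), call. = FALSE)
      next
    }
    reports[[lbl]] <- agreement_report(m_all[keep], e_all[keep],
                                       method = lbl)
  }
  if (!length(reports))
    stop("no method had at least 3 complete pairs", call. = FALSE)
  structure(list(reports = reports, dropped = dropped,
                 n_input = nrow(data)),
            class = "method_comparison")
}

#' Flatten a method comparison to a data.frame
#'
#' One row per method with all agreement statistics at full precision, in
#' the column order of the conventional method-comparison table: mean ± SD
#' of the estimates, CE ± SD with its p-value, SEE, TE, then correlation and
#' Bland–Altman quantities.
#'
#' @param x a `method_comparison`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return a data.frame.
#' @export
as.data.frame.method_comparison <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  do.call(rbind, lapply(x$reports, function(r)
    data.frame(method = r$method, n = r$n,
               estimated_mean = r$estimated_mean,
               estimated_sd = r$estimated_sd,
               ce = r$ce, ce_sd = r$ce_sd, ce_p = r$ce_p,
               see = r$see, te = r$te, pearson_r = r$pearson_r,
               fixed_bias = r$fixed_bias, loa_low = r$loa_low,
               loa_high = r$loa_high, fixed_p = r$fixed_p,
               prop_bias_r = r$prop_bias_r, prop_bias_p = r$prop_bias_p,
               stringsAsFactors = FALSE)))
}

#' @export
print.method_comparison <- function(x, digits = 2, ...) {
  r1 <- x$reports[[1L]]
  cat(sprintf("Measured VO2max: %.*f +/- %.*f mL/kg/min\n",
              digits, r1$measured_mean, digits, r1$measured_sd))
  cat(sprintf("%-10s %14s %16s %6s %6s %6s %6s\n",
              "Method", "eVO2max", "CE (p)", "SEE", "TE", "r", "n"))
  for (r in x$reports) {
    cat(sprintf("%-10s %6.*f +/- %.*f %5.*f +/- %.*f (%.2f) %6.*f %6.*f %6.*f %6d\n",
                r$method, digits, r$estimated_mean, digits, r$estimated_sd,
                digits, r$ce, digits, r$ce_sd, r$ce_p,
                digits, r$see, digits, r$te, digits, r$pearson_r, r$n))
  }
  dr <- x$dropped[x$dropped > 0]
  if (length(dr))
    cat("Dropped incomplete pairs: ",
        paste(sprintf("%s = %d", names(dr), dr), collapse = ", "), "\n",
        sep = "")
  invisible(x)
}
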