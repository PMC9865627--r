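#' Read a cohort file
#'
#' Reads a delimited cohort table (comma by default, tab via `sep`) with a
#' header, UTF-8, decimal point, and missing values as empty fields or
#' `NA`. Required columns: `id`, `age`, `sex`, `pa_score`, `hr_rest`,
#' `hr_ex1`, `hr_ex2`, `hr_ex3`, `hr_rec1`, `hr_rec2`, plus either `bmi` or
#' both `height_cm` and `weight_kg`. Optional columns: `stage3_skipped`,
#' `rpe_end_stage2`, `vo2max_measured`, `rer_max`, `hr_max_observed`,
#' `rpe_max`, `plateau`. Column order is free; extra columns pass through.
#'
#' Sex tokens are normalized via [normalize_sex()] (the 0/1 coding maps to
#' female/male, matching the regression indicator). Row-level problems —
#' unparseable numbers, unknown sex tokens, a missing `hr_ex3` on a row not
#' flagged `stage3_skipped` — are collected with their row numbers; in
#' strict mode the first problem aborts, otherwise offending rows are
#' dropped with a message and the full list is attached as attribute
#' `"row_errors"`. Duplicate ids and a malformed header are always fatal.
#'
#' @param path file path.
#' @param sep field separator (`","` default, `"\t"` for the tab dialect).
#' @param strict abort on the first row-level error?
#' @return a validated `data.frame`.
#' @export
read_cohort <- function(path, sep = ",", strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, na.strings = c("", "NA"),
                    fileEncoding = "UTF-8", check.names = TRUE)
  required <- c("id", "age", "sex", "pa_score", "hr_rest", "hr_ex1",
                "hr_ex2", "hr_ex3", "hr_rec1", "hr_rec2")
  miss <- setdiff(required, names(raw))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!("bmi" %in% names(raw)) &&
      !all(c("height_cm", "weight_kg") %in% names(raw)))
    stop("need a 'bmi' column or both 'height_cm' and 'weight_kg'",
         call. = FALSE)
  if (anyDuplicated(raw$id))
    stop("duplicate ids: ",
         paste(unique(raw$id[duplicated(raw$id)]), collapse = ", "),
         call. = FALSE)

  errors <- character(0)
  note <- function(i, msg) {
    m <- sprintf("row %d: %s", i, msg)
    if (strict) stop(m, call. = FALSE)
    errors <<- c(errors, m)
  }

  sex_norm <- rep(NA_character_, nrow(raw))
  for (i in seq_len(nrow(raw))) {
    s <- tryCatch(normalize_sex(raw$sex[i]),
                  error = function(e) conditionMessage(e))
    if (s %in% c("female", "male")) sex_norm[i] <- s else note(i, s)
  }
  raw$sex <- sex_norm

  num_cols <- intersect(
    c("age", "pa_score", "bmi", "height_cm", "weight_kg", "hr_rest",
      "hr_ex1", "hr_ex2", "hr_ex3", "hr_rec1", "hr_rec2",
      "rpe_end_stage2", "vo2max_measured", "rer_max", "hr_max_observed",
      "rpe_max"), names(raw))
  for (cn in num_cols) {
    v <- raw[[cn]]
    if (!is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(parsed))
      for (i in bad) note(i, sprintf("unparseable '%s': %s", cn, v[i]))
      raw[[cn]] <- parsed
    }
  }
  if ("stage3_skipped" %in% names(raw)) {
    raw$stage3_skipped <- raw$stage3_skipped %in% c(TRUE, "TRUE", "true", 1)
  } else raw$stage3_skipped <- FALSE
  if ("plateau" %in% names(raw))
    raw$plateau <- raw$plateau %in% c(TRUE, "TRUE", "true", 1)

  bad_ex3 <- which(is.na(raw$hr_ex3) & !raw$stage3_skipped)
  for (i in bad_ex3)
    note(i, "hr_ex3 missing but stage3_skipped is not set")

  if (length(errors)) {
    bad_rows <- unique(as.integer(sub("^row (\\d+):.*$", "\\1", errors)))
    message(sprintf("read_cohort: dropping %d row(s) with errors (%s)",
                    length(bad_rows), path))
    raw <- raw[-bad_rows, , drop = FALSE]
    rownames(raw) <- NULL
  }
  attr(raw, "row_errors") <- errors
  raw
}

#' Write a cohort (or any result table) to a delimited file
#'
#' Missing values are written as empty fields; numbers keep R's full
#' default precision so a read/write/read round-trip is lossless for values
#' with up to 15 significant digits.
#'
#' @param data a data.frame.
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path, sep = ",") {
  write.table(data, path, sep = sep, row.names = FALSE, quote = FALSE,
              na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Estimate VO2max for every row of a cohort file
#'
#' Thin pipeline wrapper: read (or accept) a cohort, run
#' [estimate_cohort()], optionally write the result table. Per-row missing
#' estimates (with reason codes) are normal output; a cohort with no
#' parseable rows is an error. A short log line reports version, row counts
#' and the active configuration.
#'
#' @param input path to a cohort file, or a data.frame.
#' @param output optional output path (CSV).
#' @param methods,coefs,cutoff,cutoff_strict,max_hr_formula,slope_min
#'   passed to [estimate_cohort()].
#' @param sep,strict passed to [read_cohort()].
#' @param quiet suppress the log line.
#' @return the result data.frame, invisibly.
#' @export
run_estimate <- function(input, output = NULL,
                         methods = c("mrm", "lem", "combined"),
                         coefs = mrm_coefficients(), cutoff = 45,
                         cutoff_strict = FALSE,
                         max_hr_formula = "tanaka", slope_min = 0.1,
                         sep = ",", strict = FALSE, quiet = FALSE) {
  cohort <- if (is.data.frame(input)) input else
    read_cohort(input, sep = sep, strict = strict)
  if (nrow(cohort) == 0) stop("no parseable rows in input", call. = FALSE)
  res <- estimate_cohort(cohort, methods = methods, coefs = coefs,
                         cutoff = cutoff, cutoff_strict = cutoff_strict,
                         max_hr_formula = max_hr_formula,
                         slope_min = slope_min)
  if (!quiet) {
    n_missing <- vapply(
      intersect(paste0("evo2max_", methods), names(res)),
      function(cn) sum(is.na(res[[cn]])), integer(1))
    message(sprintf(
      "vo2step %s | estimate | rows in %d out %d | missing: %s | cutoff %s (%s) | max HR %s",
      as.character(packageVersion("vo2step")), nrow(cohort), nrow(res),
      paste(sprintf("%s=%d", sub("evo2max_", "", names(n_missing)),
                    n_missing), collapse = " "),
      format(cutoff), if (cutoff_strict) ">" else ">=", max_hr_formula))
  }
  if (!is.null(output)) write_cohort(res, output, sep = sep)
  invisible(res)
}

#' Validate estimate columns against measured VO2max
#'
#' Reads (or accepts) a table holding a measured-VO2max column and one or
#' more estimate columns, computes a [compare_methods()] bundle, prints the
#' fixed-width comparison table (2 decimals), and optionally writes the
#' full-precision report as JSON.
#'
#' @param input path or data.frame.
#' @param output optional JSON output path (full precision).
#' @param measured name of the measured column.
#' @param estimates named character vector of estimate columns (default:
#'   every `evo2max_*` column).
#' @param sep field separator for file input.
#' @param quiet suppress printing.
#' @return the `method_comparison`, invisibly.
#' @export
run_validate <- function(input, output = NULL,
                         measured = "vo2max_measured", estimates = NULL,
                         sep = ",", quiet = FALSE) {
  data <- if (is.data.frame(input)) input else
    read.table(input, header = TRUE, sep = sep, stringsAsFactors = FALSE,
               na.strings = c("", "NA"), fileEncoding = "UTF-8")
  if (!(measured %in% names(data)))
    stop("measured column '", measured, "' not found", call. = FALSE)
  if (is.null(estimates)) {
    estimates <- grep("^evo2max_", names(data), value = TRUE)
    names(estimates) <- toupper(sub("^evo2max_", "", estimates))
    if (!length(estimates))
      stop("no estimate columns found (expected 'evo2max_*')",
           call. = FALSE)
  }
  cmp <- compare_methods(data, measured = measured, estimates = estimates)
  if (!quiet) print(cmp)
  if (!is.null(output)) {
    jsonlite::write_json(
      list(package = paste("vo2step",
                           as.character(packageVersion("vo2step"))),
           n_input = cmp$n_input, dropped = as.list(cmp$dropped),
           reports = lapply(cmp$reports, function(r) r[!vapply(
             r, is.null, logical(1))])),
      output, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  }
  invisible(cmp)
}
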