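`%||%` <- function(x, y) if (is.null(x)) y else x

# scalar numeric check used by constructors
check_num <- function(x, name, lower = -Inf, upper = Inf, allow_na = FALSE) {
  if (is.null(x) || length(x) != 1L)
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  if (is.na(x)) {
    if (allow_na) return(NA_real_)
    stop(sprintf("'%s' is missing", name), call. = FALSE)
  }
  x <- as.numeric(x)
  if (!is.finite(x) || x < lower || x > upper)
    stop(sprintf("'%s' = %s outside [%s, %s]", name, format(x), lower, upper),
         call. = FALSE)
  x
}

#' Normalize a sex token
#'
#' Maps the encodings seen in cohort files (`"F"`/`"M"`, `"0"`/`"1"`,
#' `"female"`/`"male"`, any case) to the canonical `"female"`/`"male"`.
#' The numeric coding follows the regression estimator's indicator
#' (0 = female, 1 = male); it is normalized here, at the boundary, and the
#' indicator is only reconstructed inside [estimate_mrm()].
#'
#' @param x character or numeric vector of sex tokens.
#' @return character vector with elements `"female"` or `"male"`.
#' @export
#' @examples
#' normalize_sex(c("F", "m", 0, 1, "Male"))
normalize_sex <- function(x) {
  tok <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(tok))
  out[tok %in% c("female", "f", "0", "woman", "women")] <- "female"
  out[tok %in% c("male", "m", "1", "man", "men")] <- "male"
  if (anyNA(out))
    stop("unrecognized sex token(s): ",
         paste(unique(tok[is.na(out)]), collapse = ", "), call. = FALSE)
  out
}
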