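# Shared helpers: date handling in the FAERS partial-date dialect,
# presentation rounding.

#' Classify FAERS date strings
#'
#' FAERS date fields are 8-digit `YYYYMMDD` strings, but real extracts carry
#' partial dates truncated to `YYYYMM` or `YYYY`, and blanks. Only full
#' 8-digit dates that form a valid calendar day are usable for interval
#' arithmetic; partial dates must be distinguished from blanks so exclusion
#' audits can report them separately.
#'
#' @param x character vector of raw date fields.
#' @return factor with levels `full`, `partial`, `missing`.
#' @seealso [parse_faers_date()]
#' @export
faers_date_status <- function(x) {
  x <- trimws(as.character(x))
  status <- rep("missing", length(x))
  digits <- grepl("^[0-9]+$", x)
  status[digits & nchar(x) %in% c(4L, 6L)] <- "partial"
  full <- digits & nchar(x) == 8L & !is.na(parse_faers_date(x))
  status[full] <- "full"
  # 8-digit strings that are not a real calendar day count as partial
  # (entered but unusable), not missing
  status[digits & nchar(x) == 8L & !full] <- "partial"
  factor(status, levels = c("full", "partial", "missing"))
}

#' Parse full-precision FAERS dates
#'
#' Converts 8-digit `YYYYMMDD` strings to `Date`; anything else (blank,
#' `YYYYMM`, `YYYY`, impossible days) becomes `NA`. Partial dates are
#' deliberately not padded to a month start: interval analyses must exclude
#' them, not guess them.
#'
#' @param x character vector of raw date fields.
#' @return `Date` vector with `NA` where no full-precision date is present.
#' @export
parse_faers_date <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(as.Date(NA), length(x))
  ok <- grepl("^[0-9]{8}$", x)
  out[ok] <- as.Date(x[ok], format = "%Y%m%d")
  out
}

#' Round half away from zero
#'
#' Published pharmacovigilance tables round 2.615 to 2.62, i.e. half-up,
#' whereas base [round()] rounds half to even. All presentation rounding in
#' this package goes through this helper so printed-precision comparisons
#' are well defined.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stop with a field-level message for config validation.
bad_field <- function(field, why) {
  stop(sprintf("invalid config field '%s': %s", field, why), call. = FALSE)
}
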