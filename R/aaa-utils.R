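# Shared helpers: date arithmetic and missing-value conventions used by both
# record schemas. Ages are always computed with divisor 365 (no leap
# correction), matching the published column definitions.

DAYS_PER_YEAR <- 365

#' Age in years between two dates
#'
#' Computed as calendar-day difference divided by 365 exactly, the convention
#' used throughout the colony record schemas.
#'
#' @param from,to `Date` vectors (`from` the earlier date, e.g. a birth date).
#' @return Numeric vector of ages in years.
#' @keywords internal
age_years <- function(from, to) {
  as.numeric(to - from) / DAYS_PER_YEAR
}

month_of <- function(d) {
  as.integer(format(d, "%m"))
}

# Tokens accepted as missing on read; empty string written on output.
MISSING_TOKENS <- c("", ".", "NA")

is_missing_token <- function(x) {
  is.na(x) | trimws(as.character(x)) %in% MISSING_TOKENS
}

#' Parse a date column permissively
#'
#' Accepts ISO-8601 (`YYYY-MM-DD`) and US `M/D/YYYY`; missing tokens
#' (`""`, `"."`, `"NA"`) become `NA`.
#'
#' @param x Character vector.
#' @return `Date` vector; attribute `"bad_rows"` holds indices that failed
#'   to parse.
#' @keywords internal
parse_date_col <- function(x) {
  x <- as.character(x)
  out <- rep(as.Date(NA), length(x))
  miss <- is_missing_token(x)
  iso <- as.Date(x, format = "%Y-%m-%d")
  us <- as.Date(x, format = "%m/%d/%Y")
  out[!miss] <- ifelse(!is.na(iso[!miss]), iso[!miss], us[!miss])
  out <- as.Date(out, origin = "1970-01-01")
  bad <- which(!miss & is.na(out))
  attr(out, "bad_rows") <- bad
  out
}

parse_num_col <- function(x) {
  x <- as.character(x)
  x[is_missing_token(x)] <- NA_character_
  suppressWarnings(as.numeric(x))
}

parse_int_col <- function(x) {
  v <- parse_num_col(x)
  as.integer(round(v))
}

parse_chr_col <- function(x) {
  x <- as.character(x)
  x[is_missing_token(x)] <- NA_character_
  x
}

# Format values for the published CSV layouts: NA -> "", dates ISO-8601,
# numerics without scientific notation.
format_cell <- function(x) {
  if (inherits(x, "Date")) {
    out <- format(x, "%Y-%m-%d")
  } else if (is.numeric(x)) {
    out <- vapply(x, function(v) {
      if (is.na(v)) "" else format(v, scientific = FALSE, trim = TRUE)
    }, character(1))
  } else {
    out <- as.character(x)
  }
  out[is.na(out)] <- ""
  out
}

# Round to a fixed number of decimals, returning NA for NA input.
round_or_na <- function(x, digits) {
  ifelse(is.na(x), NA_real_, round(x, digits))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
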