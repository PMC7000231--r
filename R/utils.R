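# Shared helpers: term normalization, rounding, date arithmetic.

#' Normalize a local term for lookup
#'
#' Lowercases, trims, and collapses internal whitespace. All terminology
#' lookups are exact matches on this normal form.
#'
#' @param x character vector of terms.
#' @return character vector of normalized terms.
#' @keywords internal
norm_term <- function(x) {
  tolower(gsub("\\s+", " ", trimws(as.character(x))))
}

#' Round half away from zero
#'
#' Commercial rounding (0.5 always rounds up in magnitude), as used for all
#' reported percentages: 0 decimals for disposition rates, 1 decimal for
#' prevalence rates. Base `round()` rounds half to even, which does not
#' reproduce published accounting figures in general.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_away(2.5)      # 3
#' round_half_away(3.667, 1) # 3.7
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  # the epsilon guards against binary representation pushing an exact .5
  # (e.g. 3.65 at one decimal) just below the rounding boundary
  sign(x) * floor(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse an ISO-8601 (possibly partial) date
#'
#' Full dates pass through; a year-only date resolves to July 1 of that year
#' and a year-month date to the 15th, so age arithmetic on partial dates is
#' deterministic (midpoint convention).
#'
#' @param x character vector of dates ("YYYY", "YYYY-MM", or "YYYY-MM-DD";
#'   a trailing time component is dropped).
#' @return `Date` vector; unparseable entries are `NA`.
#' @keywords internal
parse_fhir_date <- function(x) {
  x <- as.character(x)
  x <- sub("[T ].*$", "", x)
  out <- rep(as.Date(NA), length(x))
  full <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  ym <- !is.na(x) & grepl("^\\d{4}-\\d{2}$", x)
  yo <- !is.na(x) & grepl("^\\d{4}$", x)
  if (any(full)) out[full] <- as.Date(x[full])
  if (any(ym)) out[ym] <- as.Date(paste0(x[ym], "-15"))
  if (any(yo)) out[yo] <- as.Date(paste0(x[yo], "-07-01"))
  out
}

# Shift a date by whole years, clamping Feb 29 to Feb 28 when the target
# year is not a leap year.
add_years <- function(date, n) {
  y <- as.integer(format(date, "%Y")) + n
  md <- format(date, "%m-%d")
  md[md == "02-29" & !is_leap(y)] <- "02-28"
  as.Date(paste0(y, "-", md))
}

is_leap <- function(y) (y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0

#' Completed whole-year age at a reference date
#'
#' @param birth_date,as_of `Date` scalars or vectors.
#' @return integer floor age; `NA` when either date is missing.
#' @keywords internal
floor_age <- function(birth_date, as_of) {
  b <- as.POSIXlt(birth_date)
  a <- as.POSIXlt(as_of)
  age <- a$year - b$year
  not_yet <- (a$mon < b$mon) | (a$mon == b$mon & a$mday < b$mday)
  age - as.integer(not_yet)
}

# Package-level cache environment (default maps, rulesets, pattern tables).
.fhh_cache <- new.env(parent = emptyenv())

cache_get <- function(key, build) {
  if (!exists(key, envir = .fhh_cache)) {
    assign(key, build(), envir = .fhh_cache)
  }
  get(key, envir = .fhh_cache)
}
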