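#' FAERS date utilities
#'
#' FAERS encodes dates as digit strings: `YYYYMMDD` (full precision),
#' `YYYYMM` (month) or `YYYY` (year). Partial dates are kept, tagged with
#' their precision, and only full-precision dates enter day-level
#' arithmetic such as time-to-onset.
#'
#' @param x character vector of raw FAERS date strings.
#' @return `faers_date_precision()`: factor with levels
#'   `c("full", "month", "year", "none")`. `faers_date_to_date()`: a
#'   [Date] vector, `NA` where the string is not a valid full-precision
#'   calendar date.
#' @examples
#' faers_date_precision(c("20200101", "202001", "2020", "", "2020013"))
#' faers_date_to_date("20200229")
#' @name faers-dates
NULL

#' @rdname faers-dates
#' @export
faers_date_precision <- function(x) {
  x <- trimws(as.character(x))
  out <- rep("none", length(x))
  out[grepl("^[0-9]{4}$", x)] <- "year"
  out[grepl("^[0-9]{6}$", x)] <- "month"
  full <- grepl("^[0-9]{8}$", x) & !is.na(faers_date_to_date(x))
  out[full] <- "full"
  factor(out, levels = c("full", "month", "year", "none"))
}

#' @rdname faers-dates
#' @export
faers_date_to_date <- function(x) {
  x <- trimws(as.character(x))
  x[!grepl("^[0-9]{8}$", x)] <- NA_character_
  as.Date(x, format = "%Y%m%d")
}

# Difference in whole days between two full-precision FAERS dates; NA when
# either side is partial or missing.
faers_days_between <- function(later, earlier) {
  as.numeric(faers_date_to_date(later) - faers_date_to_date(earlier))
}

#' Convert FAERS age values to years
#'
#' Applies the unit codes used in the DEMO table: `DEC` decades, `YR`
#' years, `MON` months, `WK` weeks, `DY` days, `HR` hours. A missing unit
#' code is treated as years (the dominant convention in FAERS); an
#' unrecognized code yields `NA` with a warning.
#'
#' @param age numeric vector of raw ages.
#' @param age_cod character vector of unit codes.
#' @return numeric vector of ages in years.
#' @export
age_to_years <- function(age, age_cod) {
  age <- as.numeric(age)
  cod <- toupper(trimws(ifelse(is.na(age_cod) | age_cod == "", "YR", age_cod)))
  factors <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.18,
               DY = 1 / 365.25, HR = 1 / 8766)
  f <- unname(factors[cod])
  bad <- !is.na(age) & is.na(f) & !is.na(cod)
  if (any(bad)) {
    warning(sum(bad), " age value(s) with unrecognized unit code set to NA")
  }
  age * f
}

#' Convert FAERS weight values to kilograms
#'
#' `KG` is returned unchanged and `LBS` multiplied by 0.4536; other unit
#' codes yield `NA` with a warning. A missing code is treated as kg.
#'
#' @param wt numeric vector of raw weights.
#' @param wt_cod character vector of unit codes.
#' @return numeric vector of weights in kg.
#' @export
weight_to_kg <- function(wt, wt_cod) {
  wt <- as.numeric(wt)
  cod <- toupper(trimws(ifelse(is.na(wt_cod) | wt_cod == "", "KG", wt_cod)))
  out <- ifelse(cod == "KG", wt, ifelse(cod == "LBS", wt * 0.4536, NA_real_))
  bad <- !is.na(wt) & is.na(out) & !(cod %in% c("KG", "LBS"))
  if (any(bad)) {
    warning(sum(bad), " weight value(s) with unrecognized unit code set to NA")
  }
  out
}

# Case-insensitive, whitespace-trimmed canonical form used for all
# free-text matching (drug names, PT strings).
norm_text <- function(x) toupper(trimws(as.character(x)))
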