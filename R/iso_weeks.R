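#' ISO-8601 week key of a calendar date
#'
#' Maps each date to its ISO week-date coordinates: weeks start on Monday and
#' week 1 is the week containing the first Thursday of the year, so dates
#' near January 1 can belong to week 52/53 of the previous ISO year or week 1
#' of the next one (e.g. 2019-12-30 belongs to ISO week 1 of 2020).
#'
#' @param dates a `Date` vector (or anything `as.Date()` accepts).
#' @return A tibble with columns `iso_year` and `iso_week` (integers), one
#'   row per input date.
#' @examples
#' iso_week_key(as.Date(c("2019-12-30", "2016-01-01")))
#' @export
iso_week_key <- function(dates) {
  dates <- as.Date(dates)
  if (anyNA(dates)) {
    stop("iso_week_key(): input contains unparseable or missing dates")
  }
  tibble::tibble(
    iso_year = as.integer(lubridate::isoyear(dates)),
    iso_week = as.integer(lubridate::isoweek(dates))
  )
}

#' Count distinct ISO signing weeks in one calendar year
#'
#' The activity measure behind the FTE rule: the number of distinct
#' (ISO year, ISO week) pairs among a pathologist's sign-out dates within one
#' calendar year. Because ISO weeks straddle January 1, a calendar year can
#' contain up to 53 distinct keys.
#'
#' @param dates sign-out dates, all in the same calendar year.
#' @return Integer count of distinct ISO weeks.
#' @export
weeks_signed <- function(dates) {
  dates <- as.Date(dates)
  if (length(dates) == 0L) {
    return(0L)
  }
  yrs <- as.integer(format(dates, "%Y"))
  if (length(unique(yrs)) > 1L) {
    stop("weeks_signed(): dates span more than one calendar year")
  }
  key <- iso_week_key(dates)
  nrow(dplyr::distinct(key))
}

#' Activity-based full-time equivalent from signing weeks
#'
#' A pathologist who signed cases in more than 41 distinct ISO weeks of a
#' calendar year counts as one full FTE; otherwise FTE is `weeks / 48`
#' (48 signing weeks being a nominal full contract year). Signing in 24
#' weeks therefore yields 0.5 FTE.
#'
#' @param weeks integer vector of distinct ISO signing weeks, each in 0..53.
#' @return Numeric FTE in `[0, 1]`, vectorised over `weeks`.
#' @examples
#' compute_fte(c(24, 42, 0))
#' @export
compute_fte <- function(weeks) {
  if (any(weeks < 0)) {
    stop("compute_fte(): weeks must be nonnegative")
  }
  if (any(weeks > 53)) {
    stop("compute_fte(): more than 53 ISO weeks in a calendar year is impossible")
  }
  ifelse(weeks > 41, 1, weeks / 48)
}

# Monday of ISO week `week` in ISO year `iso_year` (internal; generator use).
# Jan 4 always falls in ISO week 1 of its year.
iso_week_monday <- function(iso_year, week) {
  jan4 <- as.Date(sprintf("%d-01-04", iso_year))
  monday1 <- jan4 - (as.integer(format(jan4, "%u")) - 1L)
  monday1 + 7L * (week - 1L)
}
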