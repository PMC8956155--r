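#' @title Case-level ingest
#' @name case_ingest
#' @description Read, validate and filter delimited sign-out tables into the
#'   canonical in-memory case set used by the rest of the pipeline.
NULL

CASE_CLASSES <- c("surgical", "cytology", "review", "external_referral")

# canonical fields; ancillary-count and precomputed-unit columns come on top
MANDATORY_FIELDS <- c(
  "case_id", "pathologist_id", "signout_date", "site", "case_class"
)
OPTIONAL_COUNT_FIELDS <- c("specimen_count", "block_count")

#' Read a case-level sign-out table
#'
#' Reads a delimited file (one row per finalized report), renames source
#' columns to the canonical field names via `column_map`, and validates each
#' row. Malformed rows are never dropped silently: they are collected in a
#' rejects table (with source row numbers and reasons) attached to the result
#' and summarised by [ingest_report()].
#'
#' Canonical fields: `case_id`, `pathologist_id`, `signout_date`, `site`,
#' `case_class` (one of surgical / cytology / review / external_referral),
#' and optional `specimen_count`, `block_count`. Ancillary-test counts map to
#' columns named `anc_<test>`; precomputed workload units (pass-through
#' scoring) map to columns named `pre_<metric>`.
#'
#' @param path path to a CSV/TSV file.
#' @param column_map named character vector or list, canonical field ->
#'   source column name. Must cover all mandatory fields. Source columns not
#'   named in the map are kept as-is (so `anc_*` / `pre_*` columns pass
#'   through).
#' @param delim field delimiter, default `","`.
#' @param date_format optional `strptime` format for `signout_date`; default
#'   ISO `"%Y-%m-%d"`.
#' @return A tibble of valid cases (source row order preserved) with
#'   attributes `rejected` (tibble: `row`, `field`, `reason`) and `n_read`.
#' @export
read_case_table <- function(path, column_map, delim = ",",
                            date_format = "%Y-%m-%d") {
  if (!file.exists(path)) {
    stop("read_case_table(): file not found: ", path)
  }
  column_map <- unlist(column_map)
  missing_map <- setdiff(MANDATORY_FIELDS, names(column_map))
  if (length(missing_map) > 0L) {
    stop(
      "read_case_table(): column_map is missing mandatory field(s): ",
      paste(missing_map, collapse = ", ")
    )
  }
  raw <- readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  absent <- setdiff(unname(column_map), names(raw))
  if (length(absent) > 0L) {
    stop(
      "read_case_table(): source column(s) not found in file: ",
      paste(absent, collapse = ", ")
    )
  }
  raw <- dplyr::rename(raw, !!!setNames(unname(column_map), names(column_map)))
  validate_cases(raw, date_format = date_format)
}

#' Validate an in-memory case table
#'
#' Applies the row-level checks of [read_case_table()] to a data frame built
#' in code: date parsing, nonnegative counts, non-empty identifiers, known
#' case classes. Invalid rows go to the `rejected` attribute.
#'
#' @param raw data frame with canonical column names (see
#'   [read_case_table()]); columns may be character.
#' @inheritParams read_case_table
#' @return See [read_case_table()].
#' @export
validate_cases <- function(raw, date_format = "%Y-%m-%d") {
  raw <- tibble::as_tibble(raw)
  missing_cols <- setdiff(MANDATORY_FIELDS, names(raw))
  if (length(missing_cols) > 0L) {
    stop(
      "validate_cases(): missing mandatory column(s): ",
      paste(missing_cols, collapse = ", ")
    )
  }
  n <- nrow(raw)
  rejects <- list()
  bad <- rep(FALSE, n)
  flag <- function(idx, field, reason) {
    if (any(idx)) {
      rejects[[length(rejects) + 1L]] <<- tibble::tibble(
        row = which(idx), field = field, reason = reason
      )
      bad <<- bad | idx
    }
  }

  dates <- as.Date(as.character(raw$signout_date), format = date_format)
  flag(is.na(dates), "signout_date", "unparseable date")
  flag(
    is.na(raw$pathologist_id) | !nzchar(trimws(as.character(raw$pathologist_id))),
    "pathologist_id", "empty pathologist id"
  )
  flag(
    !(as.character(raw$case_class) %in% CASE_CLASSES),
    "case_class",
    paste0("case_class not one of {", paste(CASE_CLASSES, collapse = ", "), "}")
  )
  for (fld in OPTIONAL_COUNT_FIELDS) {
    if (!fld %in% names(raw)) {
      raw[[fld]] <- 0L
    }
    v <- suppressWarnings(as.numeric(raw[[fld]]))
    v[is.na(raw[[fld]])] <- 0 # absent count means zero, not invalid
    flag(is.na(v) | v < 0, fld, "count missing/negative/non-numeric")
    raw[[fld]] <- v
  }
  anc_cols <- grep("^anc_", names(raw), value = TRUE)
  for (fld in anc_cols) {
    v <- suppressWarnings(as.numeric(raw[[fld]]))
    v[is.na(raw[[fld]])] <- 0
    flag(is.na(v) | v < 0, fld, "ancillary count negative/non-numeric")
    raw[[fld]] <- v
  }
  pre_cols <- grep("^pre_", names(raw), value = TRUE)
  for (fld in pre_cols) {
    raw[[fld]] <- suppressWarnings(as.numeric(raw[[fld]]))
  }

  out <- raw[!bad, , drop = FALSE]
  out$signout_date <- dates[!bad]
  out$case_id <- as.character(out$case_id)
  out$pathologist_id <- as.character(out$pathologist_id)
  out$site <- as.character(out$site)
  out$case_class <- as.character(out$case_class)
  rej <- if (length(rejects) > 0L) {
    dplyr::arrange(dplyr::bind_rows(rejects), .data$row)
  } else {
    tibble::tibble(row = integer(), field = character(), reason = character())
  }
  attr(out, "rejected") <- rej
  attr(out, "n_read") <- n
  out
}

#' Summarise an ingest run
#'
#' @param cases result of [read_case_table()] / [validate_cases()].
#' @return A list with `n_read`, `n_valid`, `n_rejected` and the rejects
#'   tibble.
#' @export
ingest_report <- function(cases) {
  rej <- attr(cases, "rejected")
  list(
    n_read = attr(cases, "n_read"),
    n_valid = nrow(cases),
    n_rejected = length(unique(rej$row)),
    rejected = rej
  )
}

#' Exclude non-qualifying case classes and out-of-window years
#'
#' Drops cases whose class is excluded (in the study: cancer review cases and
#' cases referred in from external laboratories) or whose sign-out date falls
#' outside the study years. Removal counts per class and year are attached so
#' no case ever disappears unaccounted; retrieve them with
#' [exclusion_report()].
#'
#' @param cases validated case tibble.
#' @param excluded_classes character vector of `case_class` values to drop;
#'   default `c("review", "external_referral")`.
#' @param study_years integer vector of calendar years to keep; `NULL` keeps
#'   all years present.
#' @return Filtered tibble with attribute `removals` (tibble: `year`,
#'   `reason`, `n`).
#' @export
apply_exclusions <- function(cases,
                             excluded_classes = c("review", "external_referral"),
                             study_years = NULL) {
  if (!is.null(study_years) && length(study_years) == 0L) {
    stop("apply_exclusions(): study_years must be non-empty or NULL")
  }
  yr <- as.integer(format(cases$signout_date, "%Y"))
  drop_class <- cases$case_class %in% excluded_classes
  drop_year <- if (is.null(study_years)) rep(FALSE, nrow(cases)) else !(yr %in% study_years)
  reason <- dplyr::case_when(
    drop_class ~ paste0("class:", cases$case_class),
    drop_year ~ "outside_study_window",
    TRUE ~ NA_character_
  )
  keep <- is.na(reason)
  removals <- tibble::tibble(year = yr[!keep], reason = reason[!keep]) |>
    dplyr::count(.data$year, .data$reason, name = "n")
  out <- cases[keep, , drop = FALSE]
  attr(out, "removals") <- removals
  attr(out, "rejected") <- attr(cases, "rejected")
  attr(out, "n_read") <- attr(cases, "n_read")
  out
}

#' Removal counts from the last exclusion pass
#'
#' @param cases result of [apply_exclusions()].
#' @return Tibble with `year`, `reason`, `n`.
#' @export
exclusion_report <- function(cases) {
  rem <- attr(cases, "removals")
  if (is.null(rem)) {
    tibble::tibble(year = integer(), reason = character(), n = integer())
  } else {
    rem
  }
}

#' Read ingest configuration (column map, site map, exclusions) from YAML/JSON
#'
#' @param path YAML or JSON file with any of the keys `column_map`
#'   (canonical field -> source column), `site_map` (list of
#'   `{site, division}`), `excluded_classes`, `study_years`.
#' @return A list with those elements (`site_map` as a tibble).
#' @export
read_ingest_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(cfg$site_map)) {
    cfg$site_map <- tibble::as_tibble(
      if (is.data.frame(cfg$site_map)) cfg$site_map else dplyr::bind_rows(cfg$site_map)
    )
  }
  if (!is.null(cfg$study_years)) {
    cfg$study_years <- as.integer(cfg$study_years)
  }
  cfg
}
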