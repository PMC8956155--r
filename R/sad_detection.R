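#' Detect significant-absence-or-departure (SAD) events
#'
#' A SAD event is a pathologist-year whose distinct ISO signing-week count is
#' more than `drop_weeks` (default 13, a quarter year) below the prior year's
#' count, *excluding* years whose prior year was itself a SAD event — the
#' exclusion avoids double-counting a departure that straddles a calendar
#' year boundary. Events are decided in ascending year order so the exclusion
#' always refers to already-decided status. A pathologist who signed in the
#' prior year but not at all in the current year counts as 0 current weeks;
#' new hires (no prior year) cannot generate an event in their first year,
#' and the first study year yields no events.
#'
#' @param weeks_by_year tibble with `pathologist_id`, `year`, `weeks_signed`
#'   (e.g. from [build_pathologist_years()]); one row per pathologist-year
#'   with signing activity.
#' @param drop_weeks event threshold: a drop must *exceed* this many weeks.
#' @param study_years years to scan; default the full range present.
#' @return Tibble `pathologist_id`, `year`, `weeks_current`, `weeks_prior`.
#' @export
detect_sad_events <- function(weeks_by_year, drop_weeks = 13,
                              study_years = NULL) {
  stopifnot(all(c("pathologist_id", "year", "weeks_signed") %in% names(weeks_by_year)))
  if (nrow(weeks_by_year) == 0L) {
    return(tibble::tibble(
      pathologist_id = character(), year = integer(),
      weeks_current = integer(), weeks_prior = integer()
    ))
  }
  if (is.null(study_years)) {
    study_years <- seq(min(weeks_by_year$year), max(weeks_by_year$year))
  }
  # complete the grid with 0-week rows; these exist only transiently here and
  # never become pathologist-years
  grid <- weeks_by_year |>
    dplyr::select("pathologist_id", "year", "weeks_signed") |>
    dplyr::filter(.data$year %in% study_years) |>
    tidyr::complete(
      .data$pathologist_id,
      year = study_years,
      fill = list(weeks_signed = 0L)
    ) |>
    dplyr::arrange(.data$pathologist_id, .data$year) |>
    dplyr::group_by(.data$pathologist_id) |>
    dplyr::mutate(weeks_prior = dplyr::lag(.data$weeks_signed)) |>
    dplyr::ungroup()

  candidate <- grid |>
    dplyr::filter(
      !is.na(.data$weeks_prior),
      .data$weeks_prior > 0L, # a never-yet-signer has no prior activity
      .data$weeks_prior - .data$weeks_signed > drop_weeks
    )
  # consecutive-year exclusion, resolved in ascending year order
  events <- candidate |>
    dplyr::group_by(.data$pathologist_id) |>
    dplyr::group_split() |>
    purrr::map(function(d) {
      d <- dplyr::arrange(d, .data$year)
      keep <- logical(nrow(d))
      last_event_year <- -Inf
      for (i in seq_len(nrow(d))) {
        if (d$year[i] - last_event_year > 1L) {
          keep[i] <- TRUE
          last_event_year <- d$year[i]
        }
      }
      d[keep, ]
    }) |>
    dplyr::bind_rows()
  if (nrow(events) == 0L) {
    return(tibble::tibble(
      pathologist_id = character(), year = integer(),
      weeks_current = integer(), weeks_prior = integer()
    ))
  }
  events |>
    dplyr::transmute(
      .data$pathologist_id, .data$year,
      weeks_current = as.integer(.data$weeks_signed),
      weeks_prior = as.integer(.data$weeks_prior)
    ) |>
    dplyr::arrange(.data$year, .data$pathologist_id)
}

#' SAD rates per group-year, period averages, and the lab-wide cumulative rate
#'
#' The SAD rate (SADR) is the number of SAD events divided by the FTE total:
#' per group-year, as a period average per group (arithmetic mean of the
#' yearly rates), and cumulatively for the whole laboratory
#' (total events over the *mean* yearly lab FTE across the event period; the
#' per-year-sum denominator is available via
#' `cumulative_denominator = "sum"`). Events are attributed to the
#' pathologist's group in the event year; an event whose pathologist has no
#' pathologist-year row in the event year (a full-year absence) is attributed
#' to their most recent prior group.
#'
#' @param events output of [detect_sad_events()].
#' @param pathologist_years output of [build_pathologist_years()].
#' @param cumulative_denominator `"mean"` (default) or `"sum"` of yearly lab
#'   FTE totals over the event period.
#' @return A list: `by_group_year` (tibble `group`, `year`, `sad_count`,
#'   `fte_total`, `sadr`), `period_by_group` (mean of yearly rates),
#'   `cumulative` (list `events`, `fte_denominator`, `rate`, `years`).
#' @export
sad_rates <- function(events, pathologist_years,
                      cumulative_denominator = c("mean", "sum")) {
  cumulative_denominator <- match.arg(cumulative_denominator)
  event_years <- setdiff(
    sort(unique(pathologist_years$year)),
    min(pathologist_years$year)
  )
  # group in event year, falling back to the latest prior year's group
  group_of <- function(pid, yr) {
    rows <- pathologist_years[
      pathologist_years$pathologist_id == pid & pathologist_years$year <= yr,
    ]
    if (nrow(rows) == 0L) {
      return(NA_integer_)
    }
    rows$group[which.max(rows$year)]
  }
  ev <- events
  ev$group <- if (nrow(ev) > 0L) {
    as.integer(purrr::map2_int(
      ev$pathologist_id, ev$year,
      function(p, y) as.integer(group_of(p, y))
    ))
  } else {
    integer()
  }

  fte_by_group_year <- pathologist_years |>
    dplyr::filter(.data$year %in% event_years) |>
    dplyr::group_by(.data$group, .data$year) |>
    dplyr::summarise(fte_total = sum(.data$fte), .groups = "drop")

  counts <- ev |>
    dplyr::count(.data$group, .data$year, name = "sad_count")
  by_group_year <- fte_by_group_year |>
    dplyr::left_join(counts, by = c("group", "year")) |>
    dplyr::mutate(
      sad_count = dplyr::coalesce(.data$sad_count, 0L),
      sadr = ifelse(.data$fte_total > 0, .data$sad_count / .data$fte_total, NA_real_)
    ) |>
    dplyr::select("group", "year", "sad_count", "fte_total", "sadr") |>
    dplyr::arrange(.data$group, .data$year)

  period_by_group <- by_group_year |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_years = dplyr::n(),
      sad_count = sum(.data$sad_count),
      mean_sadr = mean(.data$sadr, na.rm = TRUE),
      .groups = "drop"
    )

  lab_fte_by_year <- pathologist_years |>
    dplyr::filter(.data$year %in% event_years) |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(fte_total = sum(.data$fte), .groups = "drop")
  denom <- switch(cumulative_denominator,
    mean = mean(lab_fte_by_year$fte_total),
    sum = sum(lab_fte_by_year$fte_total)
  )
  cumulative <- list(
    events = nrow(ev),
    fte_denominator = denom,
    rate = nrow(ev) / denom,
    years = event_years
  )
  list(
    by_group_year = by_group_year,
    period_by_group = period_by_group,
    cumulative = cumulative
  )
}

#' Rescale a cumulative event rate to a different period length
#'
#' Linear pro-rating of a cumulative rate, e.g. a ~100% rate over 8 years
#' corresponds to 37.5% over 3 years.
#'
#' @param rate cumulative rate over `from_years`.
#' @param from_years,to_years period lengths in years.
#' @return Rescaled rate, `rate * to_years / from_years`.
#' @export
rescale_period <- function(rate, from_years, to_years) {
  stopifnot(from_years > 0, to_years > 0)
  rate * to_years / from_years
}
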