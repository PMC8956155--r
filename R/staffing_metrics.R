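#' @title Staffing metrics
#' @name staffing_metrics
#' @description Aggregate scored cases into pathologist-years (distinct ISO
#'   signing weeks, activity-based FTE, raw and pro-rata workload), assign
#'   each pathologist a hospital group per year from their case mix, and
#'   summarise group-years.
NULL

#' Default site-to-division map
#'
#' The laboratory model: four hospital sites feeding three divisions —
#' `alpha` (one hospital organization, two sites) and `beta1`/`beta2` (the
#' two parts of the other organization). Fully user-editable; the mapping of
#' divisions to the published group numbers 1/2/3 is a separate, configurable
#' permutation (see [build_pathologist_years()]).
#'
#' @return Tibble with columns `site`, `division`.
#' @export
default_site_map <- function() {
  tibble::tibble(
    site = c("site1", "site2", "site3", "site4"),
    division = c("alpha", "alpha", "beta1", "beta2")
  )
}

#' Assign a pathologist-year to a division from case-mix fractions
#'
#' Two-step yearly rule. Outer step, on *surgical* cases only: if the
#' fraction signed for organization alpha exceeds the fraction for
#' organization beta, assign alpha; else beta (ties go to beta). Inner step,
#' for beta members, on *all* qualifying cases: if the beta1 fraction exceeds
#' the beta2 fraction, assign beta1; else beta2 (ties to beta2).
#' Pathologists with no surgical cases that year (cytology-only) fall back to
#' all-case fractions for the outer step; the fallback is flagged in the
#' output of [build_pathologist_years()].
#'
#' @param surg_alpha,surg_beta fractions of the year's surgical cases from
#'   the alpha / beta organizations (vectorised).
#' @param all_alpha,all_beta1,all_beta2 fractions of all qualifying cases by
#'   division.
#' @param has_surgical logical, any surgical case signed that year.
#' @return Character vector in `{"alpha", "beta1", "beta2"}`.
#' @export
assign_division <- function(surg_alpha, surg_beta, all_alpha, all_beta1,
                            all_beta2, has_surgical) {
  outer_alpha <- ifelse(has_surgical,
    surg_alpha > surg_beta,
    all_alpha > (all_beta1 + all_beta2)
  )
  ifelse(outer_alpha, "alpha", ifelse(all_beta1 > all_beta2, "beta1", "beta2"))
}

#' Build per-pathologist per-year aggregates
#'
#' One row per (pathologist, calendar year) with at least one qualifying
#' case. Workload is credited to the finalizing pathologist. `weeks_signed`
#' counts distinct (ISO year, ISO week) keys among the year's sign-out dates;
#' `fte` applies the activity rule ([compute_fte()]); raw per-metric units
#' are annualized *pro rata* by dividing by the FTE (a half-year signer's
#' workload is doubled to a per-FTE-year basis).
#'
#' @param scored scored case tibble from [score_cases()] (after exclusions).
#' @param schema the [workload_schema()] used (for the metric names).
#' @param site_map tibble `site`, `division` (`alpha`/`beta1`/`beta2`);
#'   default [default_site_map()].
#' @param group_map named integer vector mapping divisions to published group
#'   numbers; default identity `c(alpha = 1, beta1 = 2, beta2 = 3)`. The
#'   study kept this permutation private for anonymity, hence the knob.
#' @return Tibble with columns `pathologist_id`, `year`, `n_cases`,
#'   `weeks_signed`, `fte`, `division`, `group`, `group_fallback` (TRUE when
#'   the cytology-only fallback decided the outer step), one raw-units column
#'   per metric, and one `pro_rata_<metric>` column per metric.
#' @export
build_pathologist_years <- function(scored, schema,
                                    site_map = default_site_map(),
                                    group_map = c(alpha = 1L, beta1 = 2L, beta2 = 3L)) {
  stopifnot(inherits(schema, "workload_schema"))
  if (!setequal(names(group_map), c("alpha", "beta1", "beta2")) ||
    !setequal(group_map, 1:3)) {
    stop("build_pathologist_years(): group_map must be a permutation of 1:3 over alpha/beta1/beta2")
  }
  unknown_sites <- setdiff(unique(scored$site), site_map$site)
  if (length(unknown_sites) > 0L) {
    stop(
      "build_pathologist_years(): site(s) not in site_map: ",
      paste(unknown_sites, collapse = ", ")
    )
  }
  df <- scored |>
    dplyr::left_join(site_map, by = "site") |>
    dplyr::mutate(
      year = as.integer(format(.data$signout_date, "%Y")),
      iso_key = paste(
        lubridate::isoyear(.data$signout_date),
        lubridate::isoweek(.data$signout_date)
      )
    )

  agg <- df |>
    dplyr::group_by(.data$pathologist_id, .data$year) |>
    dplyr::summarise(
      n_cases = dplyr::n(),
      weeks_signed = dplyr::n_distinct(.data$iso_key),
      n_surgical = sum(.data$case_class == "surgical"),
      surg_alpha = sum(.data$case_class == "surgical" & .data$division == "alpha"),
      surg_beta = sum(.data$case_class == "surgical" & .data$division != "alpha"),
      all_alpha = mean(.data$division == "alpha"),
      all_beta1 = mean(.data$division == "beta1"),
      all_beta2 = mean(.data$division == "beta2"),
      dplyr::across(dplyr::all_of(schema$metrics), sum),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      fte = compute_fte(.data$weeks_signed),
      group_fallback = .data$n_surgical == 0L,
      division = assign_division(
        surg_alpha = ifelse(.data$n_surgical > 0L, .data$surg_alpha / .data$n_surgical, 0),
        surg_beta = ifelse(.data$n_surgical > 0L, .data$surg_beta / .data$n_surgical, 0),
        all_alpha = .data$all_alpha,
        all_beta1 = .data$all_beta1,
        all_beta2 = .data$all_beta2,
        has_surgical = .data$n_surgical > 0L
      ),
      group = unname(group_map[.data$division])
    )
  for (m in schema$metrics) {
    agg[[paste0("pro_rata_", m)]] <- agg[[m]] / agg$fte
  }
  agg |>
    dplyr::select(
      "pathologist_id", "year", "n_cases", "weeks_signed", "fte",
      "division", "group", "group_fallback",
      dplyr::all_of(schema$metrics),
      dplyr::starts_with("pro_rata_")
    ) |>
    dplyr::arrange(.data$pathologist_id, .data$year)
}

#' Group-year summaries of pro-rata workload
#'
#' For each (group, year): the number of signers, total FTEs, total raw
#' units, units per FTE (total/total), and summary statistics — mean, sample
#' sd, median, min, max — of the members' *pro-rata* yearly units. Note the
#' mean of member pro-rata units is a different quantity from
#' `units_total / fte_total` (unweighted vs FTE-weighted); both are reported
#' under distinct names. Groups with a single member get `sd = NA`.
#'
#' @param pathologist_years result of [build_pathologist_years()].
#' @param metric metric name, default `"L4E"`.
#' @param min_fte drop pathologist-years with FTE at or below this (default 0
#'   keeps everyone); the study's sensitivity variant uses 0.3.
#' @param full_time_only if TRUE keep only `fte == 1`.
#' @return Tibble with one row per (group, year).
#' @export
group_summary <- function(pathologist_years, metric = "L4E",
                          min_fte = 0, full_time_only = FALSE) {
  pr <- paste0("pro_rata_", metric)
  if (!pr %in% names(pathologist_years)) {
    stop("group_summary(): metric '", metric, "' not present")
  }
  py <- dplyr::filter(pathologist_years, .data$fte > min_fte)
  if (full_time_only) py <- dplyr::filter(py, .data$fte == 1)
  py |>
    dplyr::group_by(.data$group, .data$year) |>
    dplyr::summarise(
      n_signers = dplyr::n(),
      fte_total = sum(.data$fte),
      units_total = sum(.data[[metric]]),
      units_per_fte = sum(.data[[metric]]) / sum(.data$fte),
      mean = mean(.data[[pr]]),
      sd = if (dplyr::n() > 1L) sd(.data[[pr]]) else NA_real_,
      median = median(.data[[pr]]),
      min = min(.data[[pr]]),
      max = max(.data[[pr]]),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$group, .data$year)
}

#' Study-period averages of yearly group summaries
#'
#' Arithmetic mean of the yearly values per group, including the mean of the
#' yearly signer counts (which is generally fractional, e.g. an `n` of 10.9).
#' Missing yearly values (single-member sd) are dropped from the average of
#' that column only.
#'
#' @param group_years result of [group_summary()] (or any per-group-year
#'   table whose non-key columns should be averaged over years).
#' @return One row per group; `year` is replaced by `n_years`.
#' @export
period_average <- function(group_years) {
  group_years |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_years = dplyr::n_distinct(.data$year),
      dplyr::across(
        dplyr::where(is.numeric) & !dplyr::any_of("year"),
        ~ mean(.x, na.rm = TRUE)
      ),
      .groups = "drop"
    )
}
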