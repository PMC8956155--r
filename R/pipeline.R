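#' Run the full workload-equity pipeline
#'
#' Orchestrates ingest/exclusion, workload scoring, pathologist-year and
#' group-year aggregation, inequality metrics, the Robin Hood FTE
#' redistribution, and SAD detection, returning all of the study-style tables
#' in one bundle. Exactly one of `cases` or `scenario` must be supplied.
#'
#' @param cases a validated case tibble (from [read_case_table()] /
#'   [validate_cases()] or [generate_lab()]), or `NULL`.
#' @param scenario a [synthetic_config()] to generate data from, or `NULL`.
#' @param schema [workload_schema()]; defaults to the scenario's schema or
#'   [illustrative_schema()].
#' @param site_map tibble `site`, `division`; default [default_site_map()].
#' @param metric headline metric, default `"L4E"`.
#' @param excluded_classes,study_years passed to [apply_exclusions()].
#' @param estimator Gini estimator, `"bias_corrected"` (default) or
#'   `"plain"`.
#' @param min_fte FTE floor for the sensitivity Gini table (default 0.3).
#' @param group_map division-to-group-number permutation, see
#'   [build_pathologist_years()].
#' @param drop_weeks SAD threshold, see [detect_sad_events()].
#' @return An object of class `report_bundle`: a list with
#'   `pathologist_years`, `group_years` (yearly), `summary_table` (period
#'   averages), `gini_full_time`, `gini_min_fte`, `robin_hood_yearly`,
#'   `robin_hood` (period table), `sad_events`, `sad_rates`,
#'   `fte_by_group_year`, `exclusions`, and `provenance`.
#' @export
run_pipeline <- function(cases = NULL, scenario = NULL,
                         schema = NULL, site_map = default_site_map(),
                         metric = "L4E",
                         excluded_classes = c("review", "external_referral"),
                         study_years = NULL,
                         estimator = c("bias_corrected", "plain"),
                         min_fte = 0.3,
                         group_map = c(alpha = 1L, beta1 = 2L, beta2 = 3L),
                         drop_weeks = 13) {
  estimator <- match.arg(estimator)
  if (is.null(cases) == is.null(scenario)) {
    stop("run_pipeline(): supply exactly one of `cases` or `scenario`")
  }
  truth <- NULL
  if (!is.null(scenario)) {
    lab <- generate_lab(scenario)
    cases <- validate_cases(lab$cases)
    truth <- lab$truth
    if (is.null(schema)) schema <- scenario$schema
  }
  if (is.null(schema)) schema <- illustrative_schema()

  kept <- apply_exclusions(cases,
    excluded_classes = excluded_classes,
    study_years = study_years
  )
  scored <- score_cases(kept, schema)
  py <- build_pathologist_years(scored, schema,
    site_map = site_map, group_map = group_map
  )
  gy <- group_summary(py, metric = metric)
  rh_yearly <- gy |>
    dplyr::group_by(.data$year) |>
    dplyr::group_split() |>
    purrr::map(robin_hood_ftes) |>
    dplyr::bind_rows()
  events <- detect_sad_events(py, drop_weeks = drop_weeks)
  rates <- sad_rates(events, py)

  bundle <- list(
    pathologist_years = py,
    group_years = gy,
    summary_table = period_average(gy),
    gini_full_time = gini_by_group(py,
      metric = metric, estimator = estimator, full_time_only = TRUE
    ),
    gini_min_fte = gini_by_group(py,
      metric = metric, estimator = estimator, min_fte = min_fte
    ),
    robin_hood_yearly = rh_yearly,
    robin_hood = robin_hood_table(gy),
    sad_events = events,
    sad_rates = rates,
    fte_by_group_year = dplyr::select(
      gy, "group", "year", "fte_total", "units_per_fte"
    ),
    exclusions = exclusion_report(kept),
    truth = truth,
    provenance = list(
      schema_version = schema$version,
      metric = metric,
      estimator = estimator,
      min_fte = min_fte,
      drop_weeks = drop_weeks,
      excluded_classes = excluded_classes,
      group_map = as.list(group_map),
      n_cases_scored = nrow(scored),
      generated = format(Sys.time(), "%Y-%m-%d %H:%M:%S", tz = "UTC")
    )
  )
  class(bundle) <- "report_bundle"
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  cat(
    "  cases scored:", x$provenance$n_cases_scored,
    "| metric:", x$provenance$metric,
    "| schema:", x$provenance$schema_version, "\n"
  )
  cat(
    "  pathologist-years:", nrow(x$pathologist_years),
    "| group-years:", nrow(x$group_years),
    "| SAD events:", nrow(x$sad_events), "\n"
  )
  cat("  period summary (per-FTE units and pro-rata statistics):\n")
  print(x$summary_table, n = Inf)
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits the tidy CSV tables, a JSON run manifest (provenance), and the two
#' headline figures (FTEs by group-year; units per FTE by group-year).
#'
#' @param bundle a `report_bundle` from [run_pipeline()].
#' @param dir output directory (created if absent).
#' @param plots also write PNG figures (default TRUE).
#' @return Invisibly, the paths written.
#' @export
write_report_bundle <- function(bundle, dir, plots = TRUE) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- list(
    pathologist_years = bundle$pathologist_years,
    group_years = bundle$group_years,
    summary_table = bundle$summary_table,
    gini_full_time = bundle$gini_full_time,
    gini_min_fte = bundle$gini_min_fte,
    robin_hood_yearly = bundle$robin_hood_yearly,
    robin_hood = bundle$robin_hood,
    sad_events = bundle$sad_events,
    sad_rates_by_group_year = bundle$sad_rates$by_group_year,
    sad_rates_period = bundle$sad_rates$period_by_group,
    exclusions = bundle$exclusions
  )
  paths <- character()
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(tables[[nm]], p)
    paths <- c(paths, p)
  }
  manifest <- c(
    bundle$provenance,
    list(sad_cumulative = bundle$sad_rates$cumulative)
  )
  mp <- file.path(dir, "run_manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths <- c(paths, mp)
  if (plots) {
    p1 <- file.path(dir, "fte_by_group_year.png")
    ggplot2::ggsave(p1, plot_fte_by_group(bundle), width = 7, height = 4.5, dpi = 150)
    p2 <- file.path(dir, "units_per_fte_by_group_year.png")
    ggplot2::ggsave(p2, plot_units_per_fte(bundle), width = 7, height = 4.5, dpi = 150)
    paths <- c(paths, p1, p2)
  }
  invisible(paths)
}

#' Headline figures
#'
#' `plot_fte_by_group()` shows total FTEs per group and year;
#' `plot_units_per_fte()` shows workload units per FTE per group and year;
#' `plot_lorenz()` draws the Lorenz curve of a workload vector against the
#' equality diagonal.
#'
#' @param bundle a `report_bundle`.
#' @return A ggplot object.
#' @export
plot_fte_by_group <- function(bundle) {
  ggplot2::ggplot(
    bundle$fte_by_group_year,
    ggplot2::aes(.data$year, .data$fte_total,
      colour = factor(.data$group), group = factor(.data$group)
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Year", y = "Full-time equivalents", colour = "Group",
      title = "FTEs by group and year"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_fte_by_group
#' @export
plot_units_per_fte <- function(bundle) {
  ggplot2::ggplot(
    bundle$fte_by_group_year,
    ggplot2::aes(.data$year, .data$units_per_fte,
      colour = factor(.data$group), group = factor(.data$group)
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Year", y = "Workload units per FTE", colour = "Group",
      title = "Workload per FTE by group and year"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_fte_by_group
#' @param x nonnegative workload vector for [plot_lorenz()].
#' @export
plot_lorenz <- function(x) {
  pts <- lorenz(x)
  ggplot2::ggplot(pts, ggplot2::aes(.data$pop_share, .data$units_share)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "Cumulative share of pathologists",
      y = "Cumulative share of workload units",
      title = "Lorenz curve"
    ) +
    ggplot2::theme_minimal()
}
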