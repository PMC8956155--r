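#' Ready-made synthetic-laboratory scenarios
#'
#' Two fixture scenarios emulating the structure of a regional laboratory
#' with three pathologist groups of unequal per-FTE workload.
#'
#' `"paperlike_full"`: nine study years (2011-2019), rosters of 10/10/11
#' full-time pathologists across divisions alpha/beta1/beta2 (about 31 FTEs),
#' intended per-FTE means 8100/6900/4200 target-metric units, within-group
#' dispersions calibrated to Gini targets 0.05/0.16/0.23, and 30 scheduled
#' drops (to 20 residual weeks) spread over 2012-2019 and allocated 10/13/7
#' to the groups; roughly a third of the drops are departures, each replaced
#' by a partial-first-year hire the following year. About 44 cases per
#' signing week yields a table of roughly 575k qualifying reports over the
#' period.
#'
#' `"paperlike_small"`: 3 groups x 4 pathologists x 4 years (2016-2019), the
#' same mean gradient, fixed illustrative dispersions, 6 cases per week, one
#' scheduled absence and one departure-plus-hire — small enough for unit
#' tests and examples.
#'
#' @param size `"small"` or `"full"`.
#' @param seed integer seed; drives both the dispersion calibration and the
#'   case generation.
#' @return A [synthetic_config()].
#' @export
paperlike_scenario <- function(size = c("small", "full"), seed = 1L) {
  size <- match.arg(size)
  seed <- as.integer(seed)
  if (size == "small") {
    groups <- list(
      synthetic_group("high-volume", "alpha", c("site1", "site2"), 4,
        mean_units_per_fte = 8100, dispersion = 0.09, surgical_share = 0.85
      ),
      synthetic_group("mid-volume", "beta1", "site3", 4,
        mean_units_per_fte = 6900, dispersion = 0.30, surgical_share = 0.80
      ),
      synthetic_group("low-volume", "beta2", "site4", 4,
        mean_units_per_fte = 4200, dispersion = 0.45, surgical_share = 0.70
      )
    )
    turnover <- tibble::tibble(
      pathologist_id = c("g1p02", "g3p03"),
      year = c(2017L, 2018L),
      residual_weeks = c(20L, 15L),
      departs = c(FALSE, TRUE)
    )
    hires <- tibble::tibble(
      pathologist_id = "g3h01", group = 3L, year = 2019L, start_week = 10L
    )
    return(synthetic_config(
      years = 2016:2019, groups = groups, turnover = turnover, hires = hires,
      cases_per_week = 6, seed = seed
    ))
  }

  sizes <- c(10L, 10L, 11L)
  means <- c(8100, 6900, 4200)
  gini_targets <- c(0.05, 0.16, 0.23)
  disp <- vapply(
    1:3,
    function(i) {
      calibrate_dispersion(gini_targets[i],
        n = sizes[i],
        seed = (seed * 13L + i) %% .Machine$integer.max
      )
    },
    0
  )
  groups <- list(
    synthetic_group("high-volume", "alpha", c("site1", "site2"), sizes[1],
      mean_units_per_fte = means[1], dispersion = disp[1], surgical_share = 0.85
    ),
    synthetic_group("mid-volume", "beta1", "site3", sizes[2],
      mean_units_per_fte = means[2], dispersion = disp[2], surgical_share = 0.80
    ),
    synthetic_group("low-volume", "beta2", "site4", sizes[3],
      mean_units_per_fte = means[3], dispersion = disp[3], surgical_share = 0.70
    )
  )

  # 30 scheduled drops over 2012-2019, allocated 10/13/7 by group (in
  # proportion to the event-rate gradient the scenario emulates); round-robin
  # member assignment guarantees no pathologist has drops in consecutive
  # years, so every scheduled drop is one SAD event downstream.
  n_drops <- c(10L, 13L, 7L)
  turnover <- purrr::map(1:3, function(gi) {
    k <- seq_len(n_drops[gi])
    member <- ((k - 1L) %% sizes[gi]) + 1L
    tibble::tibble(
      pathologist_id = sprintf("g%dp%02d", gi, member),
      year = 2012L + ((k - 1L) %% 8L),
      residual_weeks = 20L,
      member = member
    )
  }) |>
    dplyr::bind_rows()
  dup <- turnover$pathologist_id[duplicated(turnover$pathologist_id)]
  turnover$departs <- !(turnover$pathologist_id %in% dup) &
    (seq_len(nrow(turnover)) %% 3L == 0L) &
    turnover$year < 2019L
  turnover$member <- NULL
  dep <- turnover[turnover$departs, ]
  hires <- tibble::tibble(
    pathologist_id = sprintf("h%02d", seq_len(nrow(dep))),
    group = as.integer(sub("^g(\\d)p.*$", "\\1", dep$pathologist_id)),
    year = dep$year + 1L,
    start_week = 10L
  )
  synthetic_config(
    years = 2011:2019, groups = groups, turnover = turnover, hires = hires,
    cases_per_week = 44, seed = seed
  )
}
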