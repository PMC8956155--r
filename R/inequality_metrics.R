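#' Gini coefficient of a nonnegative vector
#'
#' Mean absolute difference estimator. The plain form is
#' \deqn{G = \frac{\sum_i \sum_j |x_i - x_j|}{2 n^2 \bar x},}
#' computed here via the O(n log n) sorted identity
#' \eqn{G = \frac{2 \sum_i i\,x_{(i)}}{n \sum_i x_i} - \frac{n+1}{n}}.
#' The bias-corrected form multiplies by \eqn{n/(n-1)} (the common default of
#' survey-statistics implementations); under it a vector where one member
#' holds everything scores exactly 1.
#'
#' @param x numeric vector of nonnegative values (workloads, incomes, ...).
#' @param estimator `"bias_corrected"` (default) or `"plain"`.
#' @param na.rm drop missing values first.
#' @return Gini in `[0, 1]`; `NA` with a warning when fewer than two values
#'   remain or all values are zero.
#' @export
gini <- function(x, estimator = c("bias_corrected", "plain"), na.rm = FALSE) {
  estimator <- match.arg(estimator)
  if (na.rm) x <- x[!is.na(x)]
  if (anyNA(x)) {
    return(NA_real_)
  }
  if (any(x < 0)) {
    stop("gini(): negative values are outside the domain")
  }
  n <- length(x)
  if (n < 2L) {
    warning("gini(): undefined for fewer than 2 values")
    return(NA_real_)
  }
  if (sum(x) == 0) {
    warning("gini(): undefined when all values are zero")
    return(NA_real_)
  }
  xs <- sort(x)
  g <- 2 * sum(seq_len(n) * xs) / (n * sum(xs)) - (n + 1) / n
  if (estimator == "bias_corrected") g <- g * n / (n - 1)
  g
}

#' Lorenz curve points
#'
#' Sorts ascending and returns cumulative population share against cumulative
#' units share, starting at (0, 0) and ending at (1, 1). For nonnegative
#' input the curve lies on or below the diagonal, and
#' `1 - 2 * area under the curve` (trapezoid rule) equals the plain Gini.
#'
#' @param x numeric vector of nonnegative values, `n >= 1`.
#' @return Tibble with columns `pop_share`, `units_share`.
#' @export
lorenz <- function(x) {
  if (anyNA(x) || any(x < 0)) {
    stop("lorenz(): values must be nonnegative and non-missing")
  }
  n <- length(x)
  if (n < 1L) {
    stop("lorenz(): empty input")
  }
  if (sum(x) == 0) {
    warning("lorenz(): all values zero; returning the diagonal")
    return(tibble::tibble(pop_share = c(0, seq_len(n) / n), units_share = c(0, seq_len(n) / n)))
  }
  xs <- sort(x)
  tibble::tibble(
    pop_share = c(0, seq_len(n) / n),
    units_share = c(0, cumsum(xs) / sum(xs))
  )
}

#' Hoover (Robin Hood) index
#'
#' The fraction of the total that would have to be redistributed to achieve
#' perfect equality:
#' \deqn{H = \frac{\sum_i |x_i - \bar x|}{2 \sum_i x_i}.}
#' Always satisfies \eqn{H \le G} (plain Gini).
#'
#' @inheritParams lorenz
#' @return Hoover index in `[0, 1]`; `NA` with a warning when all zero.
#' @export
hoover <- function(x) {
  if (anyNA(x) || any(x < 0)) {
    stop("hoover(): values must be nonnegative and non-missing")
  }
  if (length(x) < 1L) {
    stop("hoover(): empty input")
  }
  if (sum(x) == 0) {
    warning("hoover(): undefined when all values are zero")
    return(NA_real_)
  }
  sum(abs(x - mean(x))) / (2 * sum(x))
}

#' Yearly within-group Gini of pro-rata workload
#'
#' Computes the Gini coefficient of members' pro-rata yearly units per
#' (group, year), plus an all-groups-pooled row per year (`group = NA`).
#' The study's headline variant restricts to full-time pathologists
#' (`full_time_only = TRUE`); a `min_fte = 0.3` variant covers everyone above
#' 0.3 FTE. Members enter unweighted.
#'
#' @inheritParams group_summary
#' @param estimator passed to [gini()].
#' @return Tibble `group` (NA = all groups pooled), `year`, `n`, `gini`.
#' @export
gini_by_group <- function(pathologist_years, metric = "L4E",
                          estimator = c("bias_corrected", "plain"),
                          min_fte = 0, full_time_only = FALSE) {
  estimator <- match.arg(estimator)
  pr <- paste0("pro_rata_", metric)
  py <- dplyr::filter(pathologist_years, .data$fte > min_fte)
  if (full_time_only) py <- dplyr::filter(py, .data$fte == 1)
  per_group <- py |>
    dplyr::group_by(.data$group, .data$year) |>
    dplyr::summarise(
      n = dplyr::n(),
      gini = suppressWarnings(gini(.data[[pr]], estimator = estimator)),
      .groups = "drop"
    )
  pooled <- py |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(
      group = NA_integer_,
      n = dplyr::n(),
      gini = suppressWarnings(gini(.data[[pr]], estimator = estimator)),
      .groups = "drop"
    )
  dplyr::bind_rows(per_group, pooled) |>
    dplyr::select("group", "year", "n", "gini") |>
    dplyr::arrange(.data$group, .data$year)
}

#' Robin Hood FTE redistribution for one year
#'
#' The number of FTEs that would have to move between groups so that every
#' group carries the same workload per FTE. With pooled mean
#' \eqn{\bar w = \sum_g U_g / \sum_g F_g} (units over FTEs), group g's
#' adjustment is \eqn{U_g/\bar w - F_g}: positive means the group is
#' under-staffed for its work (a deficit — more FTEs required), negative a
#' surplus. The real-valued adjustments sum to zero by construction, and
#' applying them equalizes per-FTE workload exactly.
#'
#' @param group_years one year's rows from [group_summary()] (needs
#'   `group`, `year`, `units_total`, `fte_total`); at least one group with
#'   positive FTE.
#' @return Tibble `group`, `fte_total`, `units_total`, `adjustment_fte`,
#'   `adjustment_pct` (percent of the group's own FTEs), with attribute
#'   `grand_mean_units_per_fte`.
#' @export
robin_hood_ftes <- function(group_years) {
  if (nrow(group_years) < 1L || sum(group_years$fte_total) <= 0) {
    stop("robin_hood_ftes(): need at least one group with positive FTE")
  }
  if (sum(group_years$units_total) <= 0) {
    stop("robin_hood_ftes(): total workload is zero; redistribution undefined")
  }
  if (dplyr::n_distinct(group_years$year) > 1L) {
    stop("robin_hood_ftes(): pass a single year; see robin_hood_table() for panels")
  }
  w_bar <- sum(group_years$units_total) / sum(group_years$fte_total)
  out <- group_years |>
    dplyr::transmute(
      .data$group, .data$year, .data$fte_total, .data$units_total,
      adjustment_fte = .data$units_total / w_bar - .data$fte_total,
      adjustment_pct = 100 * (.data$units_total / w_bar - .data$fte_total) / .data$fte_total
    )
  attr(out, "grand_mean_units_per_fte") <- w_bar
  out
}

# round half away from zero (commercial rounding), not banker's rounding
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Period Robin Hood FTE table
#'
#' Computes yearly real-valued adjustments per group, averages them across
#' the study years, and presents integers that still sum to zero. Default
#' (`average_first = TRUE`): average the yearly real adjustments, then round
#' half-away-from-zero, assigning any residual to the group with the largest
#' absolute adjustment so the integer row sums to zero. The alternative
#' rounds each year first and averages after.
#'
#' @param group_years multi-year [group_summary()] output.
#' @param average_first average yearly real adjustments before rounding
#'   (default) or round yearly values first.
#' @return Tibble `group`, `adjustment_fte` (period-average real value),
#'   `adjustment_pct`, `adjustment_int` (zero-sum integers).
#' @export
robin_hood_table <- function(group_years, average_first = TRUE) {
  yearly <- group_years |>
    dplyr::group_by(.data$year) |>
    dplyr::group_split() |>
    purrr::map(robin_hood_ftes) |>
    dplyr::bind_rows()
  avg <- yearly |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      adjustment_fte = mean(.data$adjustment_fte),
      adjustment_pct = mean(.data$adjustment_pct),
      mean_rounded = mean(round_half_away(.data$adjustment_fte)),
      .groups = "drop"
    )
  base <- if (average_first) avg$adjustment_fte else avg$mean_rounded
  ints <- round_half_away(base)
  residual <- -sum(ints)
  if (residual != 0) {
    k <- which.max(abs(avg$adjustment_fte))
    ints[k] <- ints[k] + residual
  }
  avg |>
    dplyr::mutate(adjustment_int = as.integer(ints)) |>
    dplyr::select("group", "adjustment_fte", "adjustment_pct", "adjustment_int")
}
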