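#' @title Synthetic laboratory generator
#' @name synthetic_lab
#' @description Seedable generator of case-level sign-out tables with a
#'   ground-truth ledger (weeks, FTEs, groups, workload totals, scheduled
#'   departures), emulating a regional laboratory with three pathologist
#'   groups of distinct per-FTE workload and dispersion.
NULL

#' Describe one synthetic pathologist group
#'
#' @param label group label for the ledger.
#' @param division `"alpha"`, `"beta1"` or `"beta2"` (drives group
#'   assignment downstream).
#' @param sites character vector of site labels owned by the group.
#' @param n_pathologists initial roster size.
#' @param mean_units_per_fte intended mean pro-rata workload (target-metric
#'   units per FTE-year).
#' @param dispersion coefficient of variation of the within-group gamma
#'   workload distribution (0 = everyone identical); calibrate against a
#'   target Gini with [calibrate_dispersion()].
#' @param surgical_share probability a generated case is surgical (the rest
#'   are cytology).
#' @return A list of class `synthetic_group`.
#' @export
synthetic_group <- function(label, division, sites, n_pathologists,
                            mean_units_per_fte, dispersion = 0,
                            surgical_share = 0.8) {
  stopifnot(
    division %in% c("alpha", "beta1", "beta2"),
    n_pathologists >= 1, mean_units_per_fte > 0, dispersion >= 0,
    surgical_share >= 0, surgical_share <= 1
  )
  structure(
    list(
      label = label, division = division, sites = sites,
      n_pathologists = as.integer(n_pathologists),
      mean_units_per_fte = mean_units_per_fte,
      dispersion = dispersion, surgical_share = surgical_share
    ),
    class = "synthetic_group"
  )
}

#' Configure a synthetic laboratory
#'
#' @param years integer vector of consecutive study years.
#' @param groups list of [synthetic_group()]s (listed order = group numbers
#'   1, 2, 3, ...).
#' @param turnover tibble of scheduled drops: `pathologist_id`, `year`,
#'   `residual_weeks` (signing weeks in the drop year), `departs` (logical;
#'   TRUE = never signs again). A drop from full activity to fewer than
#'   `weeks_full_time - 13` residual weeks produces one SAD event downstream.
#' @param hires tibble of `pathologist_id`, `group` (index), `year`,
#'   `start_week` (first ISO week they may sign; >2 gives a partial first
#'   year).
#' @param weeks_full_time distinct signing weeks of an uninterrupted year
#'   (default 46; must be <= 49 since cases are placed in ISO weeks 2-50 to
#'   keep ISO and calendar years aligned).
#' @param cases_per_week mean finalized cases per signing week.
#' @param review_rate fraction of extra review/external-referral cases added
#'   on top of qualifying cases (these are excluded downstream and ledgered).
#' @param schema [workload_schema()] used to back-solve case attributes;
#'   default [illustrative_schema()].
#' @param target_metric metric whose units the generator controls.
#' @param noise `"gamma"` (default) or `"lognormal"` workload noise.
#' @param seed integer seed; same seed, same table.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(years, groups,
                             turnover = NULL, hires = NULL,
                             weeks_full_time = 46, cases_per_week = 44,
                             review_rate = 0.05,
                             schema = illustrative_schema(),
                             target_metric = "L4E",
                             noise = c("gamma", "lognormal"),
                             seed = 1L) {
  noise <- match.arg(noise)
  years <- sort(as.integer(years))
  stopifnot(
    length(years) >= 1L, all(diff(years) == 1L),
    weeks_full_time >= 1, weeks_full_time <= 49,
    cases_per_week > 0, review_rate >= 0,
    target_metric %in% schema$metrics
  )
  for (g in groups) {
    if (!inherits(g, "synthetic_group")) {
      stop("synthetic_config(): groups must come from synthetic_group()")
    }
  }
  empty_turnover <- tibble::tibble(
    pathologist_id = character(), year = integer(),
    residual_weeks = integer(), departs = logical()
  )
  empty_hires <- tibble::tibble(
    pathologist_id = character(), group = integer(),
    year = integer(), start_week = integer()
  )
  turnover <- if (is.null(turnover)) empty_turnover else tibble::as_tibble(turnover)
  hires <- if (is.null(hires)) empty_hires else tibble::as_tibble(hires)
  if (nrow(turnover) > 0L && any(turnover$residual_weeks > weeks_full_time)) {
    stop("synthetic_config(): residual_weeks beyond weeks_full_time is an infeasible schedule")
  }
  if (nrow(hires) > 0L && any(hires$start_week < 2L | hires$start_week > 50L)) {
    stop("synthetic_config(): hire start_week must be in 2..50")
  }
  structure(
    list(
      years = years, groups = groups, turnover = turnover, hires = hires,
      weeks_full_time = as.integer(weeks_full_time),
      cases_per_week = cases_per_week, review_rate = review_rate,
      schema = schema, target_metric = target_metric, noise = noise,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

# first schema rule matching a bare case of the given class; returns the
# linear L4E-style coefficients used for back-solving attributes
class_rule_coefs <- function(schema, metric, class) {
  probe <- tibble::tibble(case_class = class, site = NA_character_, specimen_count = 1)
  for (r in schema$rules) {
    if (rule_matches(r, probe)) {
      ctr <- r$contributions[[metric]] %||% list(base = 0, per_specimen = 0, per_block = 0)
      return(list(
        base = ctr$base %||% 0,
        per_specimen = ctr$per_specimen %||% 0,
        per_block = ctr$per_block %||% 0
      ))
    }
  }
  stop("generate_lab(): schema has no rule for case_class '", class, "'")
}

# largest-remainder apportionment: nonnegative reals -> integer counts whose
# sum equals round(sum(x))
apportion_counts <- function(x) {
  fl <- floor(x)
  k <- round(sum(x)) - sum(fl)
  out <- fl
  if (k > 0) {
    ord <- order(x - fl, decreasing = TRUE)
    out[ord[seq_len(k)]] <- out[ord[seq_len(k)]] + 1
  }
  as.integer(out)
}

# draw pro-rata workload values for the active members of one group-year via
# stratified (jittered-quantile) sampling, so that the realized sample Gini
# concentrates near the distribution's Gini even at n ~ 10
draw_pro_rata <- function(n, mean_units, cv, noise) {
  if (cv == 0 || n == 0L) {
    return(rep(mean_units, n))
  }
  u <- (sample.int(n) - 1 + runif(n)) / n
  if (noise == "gamma") {
    k <- 1 / cv^2
    qgamma(u, shape = k, rate = k / mean_units)
  } else {
    s2 <- log(1 + cv^2)
    stats::qlnorm(u, meanlog = log(mean_units) - s2 / 2, sdlog = sqrt(s2))
  }
}

#' Generate a synthetic case table with its truth ledger
#'
#' Deterministic for a fixed config seed. Each pathologist-year signs cases
#' in a known set of ISO weeks (weeks 2-50, so ISO and calendar years agree);
#' their annual pro-rata workload is drawn from a gamma (or lognormal)
#' distribution with the group mean and CV = `dispersion`, scaled by their
#' FTE, then split across cases. Case attributes (block / specimen counts)
#' are back-solved from the per-case targets under the active schema, so
#' scoring the table reproduces the ledgered totals exactly; because counts
#' are integers, each annual total is quantized to the tariff grid and the
#' ledger records the *realized* total. Scheduled drops truncate signing
#' after `residual_weeks`; departures end the career; hires start at
#' `start_week` of their first year.
#'
#' @param cfg a [synthetic_config()].
#' @return A list with `cases` (unvalidated case tibble, ready for
#'   [validate_cases()] / [apply_exclusions()]) and `truth`, a ledger list:
#'   `pathologist_years` (id, year, group, division, weeks, fte, realized
#'   units, pro-rata units), `groups` (intended parameters), `scheduled_drops`
#'   (with the expected SAD flag), `exclusions` (per year/class counts of
#'   non-qualifying cases).
#' @export
generate_lab <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()),
    add = TRUE
  )
  set.seed(cfg$seed)

  ngroups <- length(cfg$groups)
  roster <- purrr::imap(cfg$groups, function(g, gi) {
    tibble::tibble(
      pathologist_id = sprintf("g%dp%02d", gi, seq_len(g$n_pathologists)),
      group = gi, start_year = cfg$years[1], start_week = 2L
    )
  }) |> dplyr::bind_rows()
  if (nrow(cfg$hires) > 0L) {
    roster <- dplyr::bind_rows(
      roster,
      tibble::tibble(
        pathologist_id = cfg$hires$pathologist_id,
        group = as.integer(cfg$hires$group),
        start_year = as.integer(cfg$hires$year),
        start_week = as.integer(cfg$hires$start_week)
      )
    )
  }
  departures <- cfg$turnover |> dplyr::filter(.data$departs)
  roster$end_year <- max(cfg$years)
  if (nrow(departures) > 0L) {
    idx <- match(departures$pathologist_id, roster$pathologist_id)
    if (anyNA(idx)) stop("generate_lab(): turnover names unknown pathologist(s)")
    roster$end_year[idx] <- departures$year
  }

  metric <- cfg$target_metric
  coefs <- list(
    surgical = class_rule_coefs(cfg$schema, metric, "surgical"),
    cytology = class_rule_coefs(cfg$schema, metric, "cytology")
  )

  py_rows <- list()
  case_blocks <- list()
  excl_rows <- list()
  case_counter <- 0L

  for (year in cfg$years) {
    active <- roster |>
      dplyr::filter(.data$start_year <= year, .data$end_year >= year)
    for (gi in seq_len(ngroups)) {
      g <- cfg$groups[[gi]]
      members <- dplyr::filter(active, .data$group == gi)
      m <- nrow(members)
      if (m == 0L) next

      # signing weeks per member
      week_sets <- vector("list", m)
      for (i in seq_len(m)) {
        w <- sort(sample(2:50, cfg$weeks_full_time))
        if (members$start_year[i] == year && members$start_week[i] > 2L) {
          w <- w[w >= members$start_week[i]]
        }
        tr <- cfg$turnover |>
          dplyr::filter(.data$pathologist_id == members$pathologist_id[i], .data$year == !!year)
        if (nrow(tr) == 1L) w <- head(w, tr$residual_weeks)
        week_sets[[i]] <- w
      }
      weeks_n <- lengths(week_sets)
      ftes <- compute_fte(weeks_n)

      pro_rata <- draw_pro_rata(m, g$mean_units_per_fte, g$dispersion, cfg$noise)
      raw_target <- pro_rata * ftes

      for (i in seq_len(m)) {
        if (weeks_n[i] == 0L) next
        pid <- members$pathologist_id[i]
        # case volume tracks individual workload: heavier signers see more
        # cases, so per-case complexity stays comparable within the group
        lambda <- cfg$cases_per_week * pro_rata[i] / g$mean_units_per_fte
        n_per_week <- rpois(weeks_n[i], max(lambda - 1, 0)) + 1L
        n_cases <- sum(n_per_week)
        week_of_case <- rep(week_sets[[i]], n_per_week)
        dates <- iso_week_monday(year, week_of_case) + sample(0:4, n_cases, replace = TRUE)
        is_surg <- runif(n_cases) < g$surgical_share
        class <- ifelse(is_surg, "surgical", "cytology")
        sites <- sample(g$sites, n_cases, replace = TRUE)

        # every case carries its rule's base units; the remaining annual units
        # are spread over cases by exponential weights and realized as integer
        # block/specimen counts via largest-remainder apportionment, so the
        # realized total matches the drawn total to within one tariff step
        # per class
        base_of <- ifelse(class == "surgical", coefs$surgical$base, coefs$cytology$base)
        remaining <- max(raw_target[i] - sum(base_of), 0)
        wts <- rexp(n_cases)
        extra <- remaining * wts / sum(wts)
        blocks <- integer(n_cases)
        specimens <- integer(n_cases)
        realized <- numeric(n_cases)
        for (cl in c("surgical", "cytology")) {
          sel <- class == cl
          if (!any(sel)) next
          co <- coefs[[cl]]
          driver <- if (co$per_block > 0) "block" else "specimen"
          rate <- if (driver == "block") co$per_block else co$per_specimen
          cnt <- if (rate > 0) apportion_counts(extra[sel] / rate) else rep(0L, sum(sel))
          if (driver == "block") {
            blocks[sel] <- cnt
            specimens[sel] <- 1L
            realized[sel] <- co$base + co$per_block * cnt + co$per_specimen
          } else {
            specimens[sel] <- cnt
            blocks[sel] <- 0L
            realized[sel] <- co$base + co$per_specimen * cnt
          }
        }

        n_excl <- rpois(1, cfg$review_rate * n_cases)
        if (n_excl > 0L) {
          e_class <- sample(c("review", "external_referral"), n_excl, replace = TRUE)
          e_week <- sample(week_sets[[i]], n_excl, replace = TRUE)
          e_dates <- iso_week_monday(year, e_week) + sample(0:4, n_excl, replace = TRUE)
          excl_rows[[length(excl_rows) + 1L]] <-
            tibble::tibble(year = year, case_class = e_class)
        } else {
          e_class <- character()
          e_dates <- as.Date(character())
        }

        ids <- sprintf("C%08d", case_counter + seq_len(n_cases + n_excl))
        case_counter <- case_counter + n_cases + n_excl
        case_blocks[[length(case_blocks) + 1L]] <- tibble::tibble(
          case_id = ids,
          pathologist_id = pid,
          signout_date = c(dates, e_dates),
          site = c(sites, sample(g$sites, n_excl, replace = TRUE)),
          case_class = c(class, e_class),
          specimen_count = c(specimens, rep(1L, n_excl)),
          block_count = c(blocks, rep(2L, n_excl))
        )
        py_rows[[length(py_rows) + 1L]] <- tibble::tibble(
          pathologist_id = pid, year = year, group = gi,
          division = g$division,
          weeks_signed = weeks_n[i], fte = ftes[i],
          units = sum(realized), pro_rata_units = sum(realized) / ftes[i]
        )
      }
    }
  }

  cases <- dplyr::bind_rows(case_blocks) |>
    dplyr::arrange(.data$signout_date, .data$case_id)
  truth_py <- dplyr::bind_rows(py_rows) |>
    dplyr::arrange(.data$pathologist_id, .data$year)
  exclusions <- if (length(excl_rows) > 0L) {
    dplyr::bind_rows(excl_rows) |> dplyr::count(.data$year, .data$case_class, name = "n")
  } else {
    tibble::tibble(year = integer(), case_class = character(), n = integer())
  }
  drops <- cfg$turnover
  if (nrow(drops) > 0L) {
    prior_weeks <- truth_py$weeks_signed[
      match(paste(drops$pathologist_id, drops$year - 1L), paste(truth_py$pathologist_id, truth_py$year))
    ]
    drop_weeks <- truth_py$weeks_signed[
      match(paste(drops$pathologist_id, drops$year), paste(truth_py$pathologist_id, truth_py$year))
    ]
    drops$expected_sad <- !is.na(prior_weeks) & (prior_weeks - drop_weeks) > 13
  }

  list(
    cases = cases,
    truth = list(
      pathologist_years = truth_py,
      groups = tibble::tibble(
        group = seq_len(ngroups),
        label = vapply(cfg$groups, `[[`, "", "label"),
        division = vapply(cfg$groups, `[[`, "", "division"),
        n_pathologists = vapply(cfg$groups, `[[`, 0L, "n_pathologists"),
        mean_units_per_fte = vapply(cfg$groups, `[[`, 0, "mean_units_per_fte"),
        dispersion = vapply(cfg$groups, `[[`, 0, "dispersion"),
        surgical_share = vapply(cfg$groups, `[[`, 0, "surgical_share")
      ),
      scheduled_drops = drops,
      exclusions = exclusions,
      target_metric = metric,
      seed = cfg$seed
    )
  )
}

#' Calibrate workload dispersion against a target Gini
#'
#' Monotone bisection on the gamma coefficient of variation until the mean
#' simulated bias-corrected Gini of `n` stratified draws (over `replicates`
#' replicates) is within `tol` of the target.
#'
#' @param target_gini target in `[0, 0.5)`.
#' @param n group size at which the Gini will be measured.
#' @param seed integer seed for the calibration simulation.
#' @param replicates simulation replicates per bisection step (default 200).
#' @param tol acceptable |mean simulated Gini - target| (default 0.01).
#' @param noise `"gamma"` or `"lognormal"`, matching the generator.
#' @return The calibrated dispersion (CV).
#' @export
calibrate_dispersion <- function(target_gini, n, seed = 1L, replicates = 200L,
                                 tol = 0.01, noise = c("gamma", "lognormal")) {
  noise <- match.arg(noise)
  stopifnot(target_gini >= 0, target_gini < 0.5, n >= 2)
  if (target_gini == 0) {
    return(0)
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()),
    add = TRUE
  )
  set.seed(seed)
  mean_gini <- function(d) {
    mean(vapply(
      seq_len(replicates),
      function(i) gini(draw_pro_rata(n, 1, d, noise), estimator = "bias_corrected"),
      0
    ))
  }
  lo <- 0
  hi <- 0.25
  while (mean_gini(hi) < target_gini) {
    hi <- hi * 2
    if (hi > 8) stop("calibrate_dispersion(): target not bracketed; is it reachable?")
  }
  for (iter in 1:40) {
    mid <- (lo + hi) / 2
    g <- mean_gini(mid)
    if (abs(g - target_gini) <= tol) {
      return(mid)
    }
    if (g < target_gini) lo <- mid else hi <- mid
  }
  stop("calibrate_dispersion(): bisection failed to reach tolerance ", tol)
}
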