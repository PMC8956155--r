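# builds a scored case table for hand-specified signing patterns
cases_for <- function(..., year = 2018) {
  specs <- list(...)
  rows <- purrr::imap(specs, function(s, pid) {
    mondays <- labequity:::iso_week_monday(year, s$weeks)
    tibble::tibble(
      case_id = paste0(pid, "_", seq_along(s$weeks)),
      pathologist_id = pid,
      signout_date = mondays,
      site = s$site,
      case_class = s$class %||% "surgical",
      specimen_count = 1,
      block_count = s$blocks %||% 2
    )
  })
  dplyr::bind_rows(rows)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("pro-rata annualization: 24 signing weeks doubles the raw workload", {
  # 24 weekly cases of 125 units -> 3000 raw units at 0.5 FTE -> 6000 pro rata
  schema <- workload_schema(
    metrics = "L4E",
    rules = list(workload_rule("flat",
      contributions = list(L4E = list(base = 125))
    ))
  )
  cases <- cases_for(P1 = list(weeks = 3:26, site = "site1"))
  scored <- score_cases(validate_cases(cases), schema)
  py <- build_pathologist_years(scored, schema)
  expect_equal(py$weeks_signed, 24L)
  expect_equal(py$fte, 0.5)
  expect_equal(py$L4E, 3000)
  expect_equal(py$pro_rata_L4E, 6000)
})

test_that("a full-time year leaves pro-rata equal to raw units", {
  schema <- unit_schema()
  cases <- cases_for(P1 = list(weeks = 3:47, site = "site1")) # 45 weeks
  scored <- score_cases(validate_cases(cases), schema)
  py <- build_pathologist_years(scored, schema)
  expect_equal(py$fte, 1)
  expect_equal(py$pro_rata_L4E, py$L4E)
})

test_that("group assignment follows the two-step case-mix rule with ties to beta/beta2", {
  schema <- unit_schema()
  mk <- function(pid, n_alpha, n_beta1, n_beta2, class = "surgical") {
    weeks <- 3:(2 + n_alpha + n_beta1 + n_beta2)
    sites <- c(rep("site1", n_alpha), rep("site3", n_beta1), rep("site4", n_beta2))
    tibble::tibble(
      case_id = paste0(pid, seq_along(weeks)), pathologist_id = pid,
      signout_date = labequity:::iso_week_monday(2018, weeks),
      site = sites, case_class = class, specimen_count = 1, block_count = 1
    )
  }
  cases <- dplyr::bind_rows(
    mk("Palpha", 7, 3, 0), # 0.7 alpha vs 0.3 beta -> alpha
    mk("Ptie", 5, 5, 0), # 0.5 vs 0.5 -> else-branch: beta, then beta1>beta2
    mk("Pbeta2", 2, 2, 8), # beta; beta1 0.2 (of 12: 2) < beta2 8 -> beta2
    mk("Pbtie", 2, 4, 4) # beta; beta1 == beta2 -> else-branch: beta2
  )
  py <- build_pathologist_years(score_cases(validate_cases(cases), schema), schema)
  got <- setNames(py$division, py$pathologist_id)
  expect_equal(got[["Palpha"]], "alpha")
  expect_equal(got[["Ptie"]], "beta1")
  expect_equal(got[["Pbeta2"]], "beta2")
  expect_equal(got[["Pbtie"]], "beta2")
  expect_false(any(py$group_fallback))
})

test_that("cytology-only pathologists fall back to all-case fractions and are flagged", {
  schema <- unit_schema()
  cases <- cases_for(
    PCyto = list(weeks = 3:12, site = "site4", class = "cytology")
  )
  py <- build_pathologist_years(score_cases(validate_cases(cases), schema), schema)
  expect_true(py$group_fallback)
  expect_equal(py$division, "beta2")
})

test_that("the division-to-group permutation is configurable", {
  schema <- unit_schema()
  cases <- cases_for(P1 = list(weeks = 3:12, site = "site1"))
  scored <- score_cases(validate_cases(cases), schema)
  py_id <- build_pathologist_years(scored, schema)
  py_perm <- build_pathologist_years(scored, schema,
    group_map = c(alpha = 3L, beta1 = 1L, beta2 = 2L)
  )
  expect_equal(py_id$group, 1L)
  expect_equal(py_perm$group, 3L)
  expect_error(
    build_pathologist_years(scored, schema, group_map = c(alpha = 1L, beta1 = 1L, beta2 = 2L)),
    "permutation"
  )
})

test_that("group assignment is invariant to case order and duplication of the case set", {
  lab <- generate_lab(paperlike_scenario("small", seed = 31))
  schema <- illustrative_schema()
  v <- apply_exclusions(validate_cases(lab$cases))
  scored <- score_cases(v, schema)
  base <- build_pathologist_years(scored, schema)
  shuffled <- build_pathologist_years(scored[sample(nrow(scored)), ], schema)
  expect_equal(base, shuffled)
  doubled <- build_pathologist_years(dplyr::bind_rows(scored, scored), schema)
  expect_equal(
    dplyr::select(base, pathologist_id, year, group, division),
    dplyr::select(doubled, pathologist_id, year, group, division)
  )
})

test_that("work is conserved from cases through groups", {
  b <- small_bundle()
  schema <- illustrative_schema()
  per_year_cases <- b$pathologist_years |>
    dplyr::group_by(year) |>
    dplyr::summarise(total = sum(L4E))
  per_year_groups <- b$group_years |>
    dplyr::group_by(year) |>
    dplyr::summarise(total = sum(units_total))
  expect_equal(per_year_cases$total, per_year_groups$total, tolerance = 1e-9)
})

test_that("group summaries use sample statistics of members' pro-rata units", {
  schema <- workload_schema(
    metrics = "L4E",
    rules = list(workload_rule("flat", contributions = list(L4E = list(per_block = 1))))
  )
  # two full-time members at 4000 and 6000 raw units
  mk <- function(pid, per_week) {
    tibble::tibble(
      case_id = paste0(pid, 1:45), pathologist_id = pid,
      signout_date = labequity:::iso_week_monday(2018, 3:47),
      site = "site1", case_class = "surgical",
      specimen_count = 1, block_count = per_week
    )
  }
  cases <- dplyr::bind_rows(mk("A", 4000 / 45), mk("B", 6000 / 45))
  py <- build_pathologist_years(score_cases(validate_cases(cases), schema), schema)
  gs <- group_summary(py, "L4E")
  expect_equal(gs$n_signers, 2L)
  expect_equal(gs$mean, 5000)
  expect_equal(gs$sd, sqrt(2e6), tolerance = 1e-9) # 1414.2136
  expect_equal(gs$median, 5000)
  expect_equal(gs$min, 4000)
  expect_equal(gs$max, 6000)
  # single member: sd is missing, never zero
  gs1 <- group_summary(py[1, ], "L4E")
  expect_true(is.na(gs1$sd))
  expect_equal(gs1$mean, gs1$median)
})

test_that("period averages include fractional mean yearly signer counts", {
  gy <- tibble::tibble(
    group = 1L, year = c(2018L, 2019L), n_signers = c(10, 11),
    fte_total = c(10, 11), units_total = c(1, 2), units_per_fte = c(0.1, 0.2),
    mean = c(1, 2), sd = c(NA, 1), median = c(1, 2), min = c(1, 2), max = c(1, 2)
  )
  avg <- period_average(gy)
  expect_equal(avg$n_signers, 10.5)
  expect_equal(avg$n_years, 2L)
  expect_equal(avg$sd, 1) # NA yearly values drop out of that column only
})

test_that("mean of member pro-rata units differs from units_total/fte_total in general", {
  b <- small_bundle()
  gy <- b$group_years
  part_time <- gy[abs(gy$mean - gy$units_per_fte) > 1e-6, ]
  expect_gt(nrow(part_time), 0)
})
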