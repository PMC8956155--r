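test_that("Gini closed forms: equality, single holder, bias correction", {
  expect_equal(gini(c(5, 5, 5, 5), "plain"), 0)
  expect_equal(gini(c(5, 5, 5, 5), "bias_corrected"), 0)
  # one of four holds everything: plain (n-1)/n = 0.75, corrected exactly 1
  expect_equal(gini(c(1, 0, 0, 0), "plain"), 0.75)
  expect_equal(gini(c(1, 0, 0, 0), "bias_corrected"), 1)
})

test_that("Gini matches the O(n^2) pairwise oracle on random vectors", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(3:300, 1)
    x <- rexp(n) * sample(c(1, 100, 1e6), 1)
    expect_equal(gini(x, "plain"), gini_bruteforce(x), tolerance = 1e-12)
    expect_equal(
      gini(x, "bias_corrected"),
      gini_bruteforce(x, bias_corrected = TRUE),
      tolerance = 1e-12
    )
  }
})

test_that("Gini domain handling: short or degenerate input", {
  expect_warning(g1 <- gini(5), "fewer than 2")
  expect_true(is.na(g1))
  expect_warning(g0 <- gini(c(0, 0, 0)), "zero")
  expect_true(is.na(g0))
  expect_error(gini(c(1, -1)), "negative")
  expect_equal(gini(c(NA, 1, 2), na.rm = TRUE), gini(c(1, 2)))
})

test_that("Gini is scale invariant and replication invariant (plain), not translation invariant", {
  set.seed(42)
  x <- rexp(50)
  expect_equal(gini(7.3 * x, "plain"), gini(x, "plain"), tolerance = 1e-12)
  expect_equal(gini(rep(x, 4), "plain"), gini(x, "plain"), tolerance = 1e-12)
  expect_lt(gini(x + 100, "plain"), gini(x, "plain"))
})

test_that("Lorenz points bracket [0,1], stay below the diagonal, and integrate to the plain Gini", {
  x <- c(0, 0, 0, 10)
  pts <- lorenz(x)
  expect_equal(pts$pop_share[1], 0)
  expect_equal(pts$units_share[1], 0)
  expect_equal(pts$pop_share[nrow(pts)], 1)
  expect_equal(pts$units_share[nrow(pts)], 1)
  expect_equal(pts$units_share[pts$pop_share == 0.75], 0)
  eq <- lorenz(c(1, 1, 1, 1))
  expect_equal(eq$units_share, eq$pop_share)
  set.seed(43)
  for (i in 1:10) {
    x <- rexp(sample(2:200, 1))
    pts <- lorenz(x)
    expect_true(all(diff(pts$units_share) >= 0))
    expect_true(all(pts$units_share <= pts$pop_share + 1e-12))
    area <- sum(diff(pts$pop_share) *
      (head(pts$units_share, -1) + pts$units_share[-1]) / 2)
    expect_equal(1 - 2 * area, gini(x, "plain"), tolerance = 1e-9)
  }
  expect_warning(dg <- lorenz(c(0, 0)), "diagonal")
  expect_equal(dg$units_share, dg$pop_share)
})

test_that("Hoover index: closed forms and majorization bound H <= plain Gini", {
  expect_equal(hoover(c(3, 3, 3)), 0)
  expect_equal(hoover(c(1, 0)), 0.5)
  set.seed(44)
  for (i in 1:50) {
    x <- rexp(sample(2:200, 1))
    expect_lte(hoover(x), gini(x, "plain") + 1e-12)
  }
  expect_warning(h <- hoover(c(0, 0)), "zero")
  expect_true(is.na(h))
})

test_that("Robin Hood FTEs: hand example, sign convention, zero sum, equalization", {
  gy <- tibble::tibble(
    group = 1:2, year = 2018L,
    units_total = c(9000, 3000), fte_total = c(1, 1)
  )
  rh <- robin_hood_ftes(gy)
  expect_equal(attr(rh, "grand_mean_units_per_fte"), 6000)
  expect_equal(rh$adjustment_fte, c(0.5, -0.5)) # deficit positive
  expect_equal(rh$adjustment_pct, c(50, -50))
  expect_equal(sum(rh$adjustment_fte), 0, tolerance = 1e-9)
  # equal per-FTE work -> zero adjustments
  eq <- robin_hood_ftes(tibble::tibble(
    group = 1:2, year = 2018L, units_total = c(4000, 8000), fte_total = c(1, 2)
  ))
  expect_equal(eq$adjustment_fte, c(0, 0))
  # applying adjustments equalizes per-FTE workload
  set.seed(45)
  for (i in 1:20) {
    gy <- tibble::tibble(
      group = 1:4, year = 2018L,
      units_total = runif(4, 1000, 9000), fte_total = runif(4, 2, 15)
    )
    rh <- robin_hood_ftes(gy)
    expect_equal(sum(rh$adjustment_fte), 0, tolerance = 1e-9)
    w <- rh$units_total / (rh$fte_total + rh$adjustment_fte)
    expect_equal(w, rep(attr(rh, "grand_mean_units_per_fte"), 4), tolerance = 1e-9)
  }
  # single group is trivially balanced
  one <- robin_hood_ftes(tibble::tibble(
    group = 1L, year = 2018L, units_total = 5000, fte_total = 5
  ))
  expect_equal(one$adjustment_fte, 0)
  expect_error(
    robin_hood_ftes(tibble::tibble(
      group = 1L, year = 2018L, units_total = 0, fte_total = 5
    )),
    "zero"
  )
})

test_that("period Robin Hood integers round half away from zero and still sum to zero", {
  gy <- tibble::tibble(
    group = rep(1:3, 2), year = rep(c(2018L, 2019L), each = 3),
    units_total = c(9000, 6000, 3000, 9600, 6000, 2400),
    fte_total = rep(1, 6)
  )
  tab <- robin_hood_table(gy)
  expect_equal(sum(tab$adjustment_int), 0L)
  expect_equal(sum(tab$adjustment_fte), 0, tolerance = 1e-9)
  # rounding residual goes to the group of largest absolute adjustment
  gy2 <- tibble::tibble(
    group = 1:3, year = 2018L,
    units_total = c(7500, 6000, 4500), fte_total = c(1, 1, 1)
  )
  tab2 <- robin_hood_table(gy2)
  expect_equal(sum(tab2$adjustment_int), 0L)
})

test_that("full-time-only and >0.3-FTE Gini variants differ when part-timers exist", {
  # one part-time outlier at 0.4 FTE with extreme pro-rata workload
  schema <- workload_schema(
    metrics = "L4E",
    rules = list(workload_rule("flat", contributions = list(L4E = list(per_block = 1))))
  )
  mk <- function(pid, weeks, per_week) {
    tibble::tibble(
      case_id = paste0(pid, seq_along(weeks)), pathologist_id = pid,
      signout_date = labequity:::iso_week_monday(2018, weeks),
      site = "site1", case_class = "surgical",
      specimen_count = 1, block_count = per_week
    )
  }
  cases <- dplyr::bind_rows(
    mk("A", 3:47, 100), mk("B", 3:47, 120), mk("C", 3:47, 110),
    mk("D", 3:21, 400) # 19 weeks ~ 0.396 FTE, huge pro-rata units
  )
  py <- build_pathologist_years(score_cases(validate_cases(cases), schema), schema)
  g_ft <- gini_by_group(py, "L4E", full_time_only = TRUE)
  g_03 <- gini_by_group(py, "L4E", min_fte = 0.3)
  pooled_ft <- g_ft$gini[is.na(g_ft$group)]
  pooled_03 <- g_03$gini[is.na(g_03$group)]
  expect_false(isTRUE(all.equal(pooled_ft, pooled_03)))
  expect_gt(pooled_03, pooled_ft)
})
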