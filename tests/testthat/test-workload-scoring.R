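test_that("hand arithmetic: surgical base 1 + 0.5/block with 4 blocks scores 3.0", {
  v <- score_case(
    list(case_class = "surgical", specimen_count = 1, block_count = 4),
    unit_schema()
  )
  expect_equal(unname(v["L4E"]), 3.0)
  expect_equal(unname(v["cases"]), 1.0)
})

test_that("precomputed units win over rules (pass-through mode)", {
  case <- tibble::tibble(
    case_id = "X", case_class = "surgical", site = "site1",
    specimen_count = 1, block_count = 4, pre_L4E = 2.5
  )
  scored <- score_cases(case, unit_schema())
  expect_equal(scored$L4E, 2.5)
  expect_equal(scored$cases, 1.0) # other metrics still rule-scored
})

test_that("a counting metric scores 1 per case and totals the case count", {
  cases <- random_cases(100, seed = 21)
  scored <- score_cases(cases, unit_schema())
  expect_true(all(scored$cases == 1))
  expect_equal(unname(metric_totals(scored, unit_schema())["cases"]), 100)
})

test_that("first-match semantics: rule order decides the category", {
  schema_a <- workload_schema(
    metrics = "L4E",
    rules = list(
      workload_rule("big", case_class = "surgical", specimen_min = 3,
        contributions = list(L4E = list(base = 10))
      ),
      workload_rule("any surgical", case_class = "surgical",
        contributions = list(L4E = list(base = 1))
      )
    )
  )
  big <- score_case(list(case_class = "surgical", specimen_count = 5), schema_a)
  small <- score_case(list(case_class = "surgical", specimen_count = 1), schema_a)
  expect_equal(unname(big), 10)
  expect_equal(unname(small), 1)
})

test_that("unmatched cases follow the configured policy", {
  lone <- tibble::tibble(
    case_id = "L1", case_class = "review", site = "site1",
    specimen_count = 1, block_count = 0
  )
  strict <- workload_schema(
    metrics = "L4E",
    rules = list(workload_rule("surgical only",
      case_class = "surgical",
      contributions = list(L4E = list(base = 1))
    )),
    unmatched = "error"
  )
  expect_error(score_cases(lone, strict), "L1")
  lax <- workload_schema(
    metrics = "L4E",
    rules = strict$rules, unmatched = "zero"
  )
  expect_warning(scored <- score_cases(lone, lax), "unmatched")
  expect_equal(scored$L4E, 0)
  expect_equal(attr(scored, "n_unmatched"), 1L)
})

test_that("random tariff totals match an independently coded brute-force loop", {
  schema <- workload_schema(
    metrics = c("L4E", "fees"),
    rules = list(
      workload_rule("surg small",
        case_class = "surgical", specimen_max = 2,
        contributions = list(
          L4E = list(base = 1, per_block = 0.7, per_ancillary = c(ihc = 0.25)),
          fees = list(base = 20, per_specimen = 3)
        )
      ),
      workload_rule("surg large",
        case_class = "surgical",
        contributions = list(
          L4E = list(base = 2.5, per_block = 0.9),
          fees = list(base = 40, per_block = 5)
        )
      ),
      workload_rule("cyto",
        case_class = "cytology",
        contributions = list(
          L4E = list(base = 0.5, per_specimen = 0.3, per_ancillary = c(ihc = 0.1)),
          fees = list(base = 10)
        )
      )
    )
  )
  cases <- random_cases(50, seed = 22)
  scored <- score_cases(cases, schema)
  # brute force: per-case if/else chain, plain loops
  exp_l4e <- exp_fees <- numeric(50)
  for (i in 1:50) {
    cc <- cases$case_class[i]
    sp <- cases$specimen_count[i]
    bl <- cases$block_count[i]
    ih <- cases$anc_ihc[i]
    if (cc == "surgical" && sp <= 2) {
      exp_l4e[i] <- 1 + 0.7 * bl + 0.25 * ih
      exp_fees[i] <- 20 + 3 * sp
    } else if (cc == "surgical") {
      exp_l4e[i] <- 2.5 + 0.9 * bl
      exp_fees[i] <- 40 + 5 * bl
    } else {
      exp_l4e[i] <- 0.5 + 0.3 * sp + 0.1 * ih
      exp_fees[i] <- 10
    }
  }
  expect_equal(scored$L4E, exp_l4e, tolerance = 1e-12)
  expect_equal(scored$fees, exp_fees, tolerance = 1e-12)
  expect_equal(
    unname(metric_totals(scored, schema)),
    c(sum(exp_l4e), sum(exp_fees)),
    tolerance = 1e-9
  )
})

test_that("scoring is additive and permutation invariant; empty input totals zero", {
  schema <- unit_schema()
  cases <- random_cases(60, seed = 23)
  whole <- metric_totals(score_cases(cases, schema), schema)
  parts <- metric_totals(score_cases(cases[1:25, ], schema), schema) +
    metric_totals(score_cases(cases[26:60, ], schema), schema)
  expect_equal(whole, parts, tolerance = 1e-12)
  perm <- metric_totals(score_cases(cases[sample(60), ], schema), schema)
  expect_equal(whole, perm, tolerance = 1e-12)
  empty <- metric_totals(score_cases(cases[0, ], schema), schema)
  expect_equal(unname(empty), c(0, 0))
})

test_that("adding a block never decreases any metric under nonnegative tariffs", {
  schema <- unit_schema()
  cases <- random_cases(40, seed = 24)
  plus <- dplyr::mutate(cases, block_count = block_count + 1)
  s0 <- score_cases(cases, schema)
  s1 <- score_cases(plus, schema)
  expect_true(all(s1$L4E >= s0$L4E))
  expect_true(all(s1$cases >= s0$cases))
})

test_that("negative tariff terms are refused at construction", {
  expect_error(
    workload_rule("bad", contributions = list(L4E = list(base = -1))),
    "nonnegative"
  )
})

test_that("the bundled illustrative schema file parses and matches the in-code schema", {
  path <- system.file("extdata", "schema_illustrative.yaml", package = "labequity")
  from_file <- read_workload_schema(path)
  in_code <- illustrative_schema()
  cases <- random_cases(30, seed = 25)
  expect_equal(
    score_cases(cases, from_file)[from_file$metrics],
    score_cases(cases, in_code)[in_code$metrics]
  )
})
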