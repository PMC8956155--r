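# shared fixtures and independent oracles

# independent ISO week oracle: glibc strftime, not lubridate
strftime_iso_key <- function(d) {
  data.frame(
    iso_year = as.integer(format(as.Date(d), "%G")),
    iso_week = as.integer(format(as.Date(d), "%V"))
  )
}

# O(n^2) brute-force pairwise Gini (the definition, no sorting shortcut);
# row-wise accumulation keeps the n^2 additions numerically honest
gini_bruteforce <- function(x, bias_corrected = FALSE) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) {
    s <- s + sum(abs(x[i] - x))
  }
  g <- s / (2 * n^2 * mean(x))
  if (bias_corrected) g <- g * n / (n - 1)
  g
}

# minimal valid case tibble for ingest/scoring tests
toy_cases <- function() {
  tibble::tibble(
    case_id = sprintf("C%03d", 1:6),
    pathologist_id = c("A", "A", "B", "B", "B", "C"),
    signout_date = as.Date(c(
      "2019-01-07", "2019-01-08", "2019-03-04",
      "2019-03-05", "2019-07-15", "2019-07-16"
    )),
    site = c("site1", "site1", "site3", "site3", "site4", "site4"),
    case_class = c(
      "surgical", "cytology", "surgical",
      "review", "surgical", "external_referral"
    ),
    specimen_count = c(1, 2, 1, 1, 3, 1),
    block_count = c(4, 0, 2, 1, 6, 0)
  )
}

write_toy_csv <- function(df, path = tempfile(fileext = ".csv")) {
  readr::write_csv(df, path)
  path
}

# one-metric schema used in hand-arithmetic tests: surgical 1 + 0.5/block
unit_schema <- function(unmatched = "error") {
  workload_schema(
    metrics = c("L4E", "cases"),
    rules = list(
      workload_rule("surgical",
        case_class = "surgical",
        contributions = list(
          L4E = list(base = 1, per_block = 0.5),
          cases = list(base = 1)
        )
      ),
      workload_rule("anything",
        contributions = list(
          L4E = list(base = 2),
          cases = list(base = 1)
        )
      )
    ),
    unmatched = unmatched,
    version = "test"
  )
}

# random tariff + random cases for brute-force scoring oracle
random_cases <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    case_id = sprintf("R%04d", seq_len(n)),
    pathologist_id = sample(LETTERS[1:4], n, replace = TRUE),
    signout_date = as.Date("2018-01-01") + sample(0:360, n, replace = TRUE),
    site = sample(c("site1", "site3", "site4"), n, replace = TRUE),
    case_class = sample(c("surgical", "cytology"), n, replace = TRUE),
    specimen_count = sample(0:5, n, replace = TRUE),
    block_count = sample(0:12, n, replace = TRUE),
    anc_ihc = sample(0:3, n, replace = TRUE)
  )
}

# cached small-scenario pipeline run for the heavier integration tests
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- run_pipeline(scenario = paperlike_scenario("small", seed = 42))
    }
    cache
  }
})
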