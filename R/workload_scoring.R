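#' Declarative workload tariff
#'
#' A `workload_schema` maps case attributes to units for one or more metrics
#' (e.g. L4E-style points, shadow-billing fee units, block counts, case
#' counts). It is an ordered list of rules with *first-match* semantics: each
#' case is scored by the first rule whose predicate it satisfies, mirroring
#' tariff tables in which every case belongs to exactly one category. The
#' real CAP-ACP L4E 2018 tariff and the Ontario Schedule of Benefits are not
#' reproduced here; the bundled example schema is illustrative and fully
#' user-editable.
#'
#' @param metrics ordered character vector of metric names.
#' @param rules list of rules from [workload_rule()].
#' @param unmatched what to do with a case no rule matches: `"error"` (stop,
#'   naming the case) or `"zero"` (score a zero vector and count a warning).
#' @param version free-text version tag recorded in outputs.
#' @return An object of class `workload_schema`.
#' @seealso [workload_rule()], [score_cases()], [read_workload_schema()]
#' @export
workload_schema <- function(metrics, rules, unmatched = c("error", "zero"),
                            version = "unversioned") {
  unmatched <- match.arg(unmatched)
  stopifnot(is.character(metrics), length(metrics) >= 1L, !anyDuplicated(metrics))
  for (r in rules) {
    if (!inherits(r, "workload_rule")) {
      stop("workload_schema(): every rule must come from workload_rule()")
    }
    extra <- setdiff(names(r$contributions), metrics)
    if (length(extra) > 0L) {
      stop(
        "workload_schema(): rule '", r$name, "' contributes to unknown metric(s): ",
        paste(extra, collapse = ", ")
      )
    }
  }
  structure(
    list(
      metrics = metrics, rules = rules,
      unmatched = unmatched, version = version
    ),
    class = "workload_schema"
  )
}

#' One tariff rule
#'
#' A predicate on case fields plus, per metric, a linear contribution
#' `base + per_specimen * specimen_count + per_block * block_count +
#' sum(per_ancillary * ancillary counts)`. All terms must be nonnegative.
#'
#' @param name rule label (shown in errors).
#' @param case_class,site optional character vectors; a case matches when its
#'   value is in the set (NULL = any).
#' @param specimen_min,specimen_max inclusive bounds on `specimen_count`.
#' @param contributions named list, metric -> list/vector with any of `base`,
#'   `per_specimen`, `per_block`, and `per_ancillary` (itself a named numeric
#'   vector, ancillary test -> units per count).
#' @return An object of class `workload_rule`.
#' @export
workload_rule <- function(name, case_class = NULL, site = NULL,
                          specimen_min = 0, specimen_max = Inf,
                          contributions = list()) {
  contributions <- lapply(contributions, function(ctr) {
    ctr <- as.list(ctr)
    out <- list(
      base = ctr$base %||% 0,
      per_specimen = ctr$per_specimen %||% 0,
      per_block = ctr$per_block %||% 0,
      per_ancillary = unlist(ctr$per_ancillary) %||% numeric()
    )
    vals <- c(out$base, out$per_specimen, out$per_block, out$per_ancillary)
    if (any(vals < 0)) {
      stop("workload_rule('", name, "'): contributions must be nonnegative")
    }
    out
  })
  structure(
    list(
      name = name, case_class = case_class, site = site,
      specimen_min = specimen_min, specimen_max = specimen_max,
      contributions = contributions
    ),
    class = "workload_rule"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rule_matches <- function(rule, cases) {
  ok <- rep(TRUE, nrow(cases))
  if (!is.null(rule$case_class)) ok <- ok & cases$case_class %in% rule$case_class
  if (!is.null(rule$site)) ok <- ok & cases$site %in% rule$site
  ok & cases$specimen_count >= rule$specimen_min &
    cases$specimen_count <= rule$specimen_max
}

#' Score a case table under a workload schema
#'
#' Applies first-match rule semantics case by case (vectorised internally)
#' and appends one numeric column per metric. Where a case carries a
#' precomputed value for a metric (column `pre_<metric>`, non-missing), the
#' precomputed value wins for that metric — pass-through mode for data whose
#' units were scored upstream.
#'
#' @param cases validated case tibble (see [read_case_table()]).
#' @param schema a [workload_schema()].
#' @return `cases` with one added column per metric, plus attribute
#'   `n_unmatched` (count of zero-scored unmatched cases under policy
#'   `"zero"`).
#' @export
score_cases <- function(cases, schema) {
  stopifnot(inherits(schema, "workload_schema"))
  clash <- intersect(schema$metrics, names(cases))
  if (length(clash) > 0L) {
    stop(
      "score_cases(): case table already has column(s) named after metric(s): ",
      paste(clash, collapse = ", ")
    )
  }
  n <- nrow(cases)
  rule_idx <- rep(NA_integer_, n)
  for (i in seq_along(schema$rules)) {
    open <- is.na(rule_idx)
    if (!any(open)) break
    hit <- open & rule_matches(schema$rules[[i]], cases)
    rule_idx[hit] <- i
  }
  unmatched <- is.na(rule_idx)
  if (any(unmatched) && schema$unmatched == "error") {
    stop(
      "score_cases(): no rule matches case(s) ",
      paste(head(cases$case_id[unmatched], 5L), collapse = ", "),
      if (sum(unmatched) > 5L) " ..." else ""
    )
  }
  if (any(unmatched)) {
    warning("score_cases(): ", sum(unmatched), " unmatched case(s) scored as zero")
  }

  anc_cols <- grep("^anc_", names(cases), value = TRUE)
  for (m in schema$metrics) {
    base <- vapply(schema$rules, function(r) r$contributions[[m]]$base %||% 0, 0)
    per_spec <- vapply(schema$rules, function(r) r$contributions[[m]]$per_specimen %||% 0, 0)
    per_blk <- vapply(schema$rules, function(r) r$contributions[[m]]$per_block %||% 0, 0)
    u <- rep(0, n)
    ok <- !unmatched
    ri <- rule_idx[ok]
    u[ok] <- base[ri] +
      per_spec[ri] * cases$specimen_count[ok] +
      per_blk[ri] * cases$block_count[ok]
    for (ac in anc_cols) {
      anc_name <- sub("^anc_", "", ac)
      per_anc <- vapply(schema$rules, function(r) {
        pa <- r$contributions[[m]]$per_ancillary
        if (!is.null(pa) && anc_name %in% names(pa)) pa[[anc_name]] else 0
      }, 0)
      u[ok] <- u[ok] + per_anc[ri] * cases[[ac]][ok]
    }
    pre_col <- paste0("pre_", m)
    if (pre_col %in% names(cases)) {
      pre <- cases[[pre_col]]
      u[!is.na(pre)] <- pre[!is.na(pre)]
    }
    cases[[m]] <- u
  }
  attr(cases, "n_unmatched") <- sum(unmatched)
  cases
}

#' Score a single case
#'
#' @param case a one-row case tibble or named list of case fields.
#' @inheritParams score_cases
#' @return Named numeric vector of units, one element per schema metric.
#' @export
score_case <- function(case, schema) {
  case <- tibble::as_tibble(as.list(case))
  if (!"specimen_count" %in% names(case)) case$specimen_count <- 0
  if (!"block_count" %in% names(case)) case$block_count <- 0
  if (!"case_id" %in% names(case)) case$case_id <- "<case>"
  if (!"site" %in% names(case)) case$site <- NA_character_
  scored <- score_cases(case, schema)
  unlist(scored[1, schema$metrics])
}

#' Total units per metric
#'
#' @param scored result of [score_cases()].
#' @param schema the schema used for scoring.
#' @return Named numeric vector of per-metric totals.
#' @export
metric_totals <- function(scored, schema) {
  vapply(schema$metrics, function(m) sum(scored[[m]]), 0)
}

#' Read a workload schema from YAML or JSON
#'
#' File layout: top-level keys `metrics` (list of names), `unmatched`,
#' `version`, and `rules` — each rule with `name`, optional `case_class`,
#' `site`, `specimen_min`, `specimen_max`, and a `contributions` map
#' metric -> `{base, per_specimen, per_block, per_ancillary: {test: units}}`.
#'
#' @param path schema file path.
#' @return A [workload_schema()].
#' @export
read_workload_schema <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  rules <- lapply(raw$rules, function(r) {
    workload_rule(
      name = r$name,
      case_class = unlist(r$case_class),
      site = unlist(r$site),
      specimen_min = r$specimen_min %||% 0,
      specimen_max = r$specimen_max %||% Inf,
      contributions = r$contributions %||% list()
    )
  })
  workload_schema(
    metrics = unlist(raw$metrics),
    rules = rules,
    unmatched = raw$unmatched %||% "error",
    version = raw$version %||% "unversioned"
  )
}

#' Illustrative workload schema
#'
#' A small, clearly labelled *illustrative* tariff used by the synthetic
#' generator and the examples: it is NOT the CAP-ACP L4E 2018 point table
#' nor the Ontario fee schedule. Metrics: `L4E` (workload points), `fees`
#' (shadow-billing units), `blocks`, `cases`.
#'
#' @return A [workload_schema()].
#' @export
illustrative_schema <- function() {
  workload_schema(
    metrics = c("L4E", "fees", "blocks", "cases"),
    rules = list(
      workload_rule(
        "surgical",
        case_class = "surgical",
        contributions = list(
          L4E = list(base = 1, per_block = 0.8),
          fees = list(base = 25, per_block = 12),
          blocks = list(per_block = 1),
          cases = list(base = 1)
        )
      ),
      workload_rule(
        "cytology",
        case_class = "cytology",
        contributions = list(
          L4E = list(base = 0.6, per_specimen = 0.4),
          fees = list(base = 15, per_specimen = 8),
          blocks = list(per_block = 1),
          cases = list(base = 1)
        )
      ),
      workload_rule(
        "review_or_referral",
        case_class = c("review", "external_referral"),
        contributions = list(
          L4E = list(base = 1.5),
          fees = list(base = 20),
          blocks = list(per_block = 1),
          cases = list(base = 1)
        )
      )
    ),
    unmatched = "error",
    version = "illustrative-0.1"
  )
}
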