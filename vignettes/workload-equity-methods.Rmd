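---
title: "Measuring workload equity in a pathology laboratory: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring workload equity in a pathology laboratory: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(labequity)
library(dplyr)
```

## The problem

Hospital pathologists are typically salaried, so the distribution of
professional work among them is rarely measured, let alone published. Yet a
laboratory information system records, for every finalized report, who signed
it, when, where the case originated, and attributes (specimens, tissue
blocks, ancillary tests) from which workload-point systems such as the
Canadian *Level 4 Equivalent* (L4E) score professional effort. From nothing
more than these sign-out records one can ask three questions:

1. How much work does each pathologist and each hospital group do, per
   full-time equivalent (FTE)?
2. How unequally is that work distributed, within and between groups?
3. How often do pathologists significantly reduce or stop signing — a
   turnover-like signal visible without any employment records?

`labequity` implements that analysis as a reusable pipeline: declarative
workload scoring, activity-based FTEs, yearly group assignment from case mix,
Gini/Lorenz/Hoover inequality measures, a zero-sum "Robin Hood FTE"
redistribution, and significant-absence-or-departure (SAD) event detection —
plus a synthetic-laboratory generator with a ground-truth ledger so every
stage can be validated end to end.

## Workload scoring

A `workload_schema()` is an ordered list of rules. Each rule matches on case
fields (class, site, specimen-count range) and contributes, per metric,

$$\text{units} = \text{base} + \text{per\_specimen}\cdot s +
  \text{per\_block}\cdot b + \sum_a \text{per\_ancillary}_a \cdot n_a .$$

Rules use **first-match** semantics — tariff tables place each case in
exactly one category — so rule order is significant. Multiple metrics (L4E
points, shadow-billing fee units, blocks, case counts) ride through the same
mechanism. Two things the schema deliberately does *not* do:

* The real CAP-ACP L4E 2018 point table and the Ontario Schedule of Benefits
  are licensed tariffs not reproduced here; the bundled
  `illustrative_schema()` (and `inst/extdata/schema_illustrative.yaml`) is
  clearly labelled illustrative, and real analyses should supply their own
  schema file.
* Work by pathologists who report ancillary studies without finalizing the
  case is not credited to them; all units of a case go to the finalizing
  signature. This mirrors how sign-out data attributes work and is a known
  limitation.

Per-case precomputed units (columns `pre_<metric>`) win over rules, so tables
scored upstream pass through unchanged.

## Activity-based FTEs and pro-rata workload

The FTE definition needs no employment records: count the distinct ISO-8601
weeks in which a pathologist signed at least one case during a calendar year.
More than 41 signing weeks counts as one FTE (full-timers have six or more
weeks off); otherwise FTE = weeks/48 (contract pathologists typically take
four weeks), so 24 signing weeks is 0.5 FTE. ISO weeks start on Monday and
week 1 contains the year's first Thursday, so a date such as 2019-12-30
belongs to ISO week 1 of 2020; we count distinct (ISO year, ISO week) keys
among the *calendar* year's dates, which allows up to 53 keys in a year.

A pathologist-year's raw units divided by its FTE gives *pro-rata* yearly
units — the workload the person carried per FTE-year, comparable across
full- and part-timers. Group-level per-FTE workload is the FTE-weighted
version (total units / total FTEs); both are reported under distinct names
because they differ whenever part-timers exist.

## Group assignment

Groups are re-derived every year from case mix alone. Outer step, surgical
cases only: a pathologist whose fraction of surgical cases from hospital
organization *alpha* exceeds the *beta* fraction is assigned alpha, else beta
(ties to beta). Inner step for beta members, on all qualifying cases: beta1
if that fraction exceeds beta2's, else beta2 (ties to beta2). A
cytology-only pathologist has no surgical fractions; we fall back to all-case
fractions for the outer step and flag the row (`group_fallback`). The
mapping of divisions alpha/beta1/beta2 to published group numbers 1/2/3 is a
configurable permutation (identity by default) because real deployments may
wish to hide it for anonymity.

## Inequality and redistribution

For members' pro-rata units \(x_1,\dots,x_n\):

* **Gini**: \(G = \sum_{i,j}|x_i-x_j| / (2n^2\bar x)\), computed by the
  sorted O(n log n) identity; the bias-corrected estimator multiplies by
  \(n/(n-1)\) and is the default (a single holder of everything then scores
  exactly 1, and it matches the common default of survey-statistics
  implementations). Both estimators are exposed.
* **Lorenz**: cumulative population share vs cumulative units share;
  \(1 - 2\times\)area under the curve equals the plain Gini (checked to
  1e-9 in tests).
* **Hoover**: \(H = \sum_i |x_i-\bar x| / (2\sum_i x_i)\), the fraction of
  units that must move to reach equality; always \(H \le G\).

The headline Gini table uses full-time pathologists only (`fte == 1`
exactly); a sensitivity variant admits everyone above 0.3 FTE. Members enter
unweighted; an FTE-weighted Gini is deliberately not used for the headline
table.

**Robin Hood FTEs.** With group totals \(U_g\) (units) and \(F_g\) (FTEs)
and pooled mean \(\bar w = \sum_g U_g / \sum_g F_g\), the adjustment
\(A_g = U_g/\bar w - F_g\) is the number of FTEs the group would need to
gain (positive, a deficit) or shed (negative, a surplus) for every group to
carry \(\bar w\) units per FTE. By construction \(\sum_g A_g = 0\) and
\(U_g / (F_g + A_g) = \bar w\) exactly. Period tables average the yearly
real-valued adjustments and then round half-away-from-zero, assigning any
residual to the group with the largest absolute adjustment so the integer
row also sums to zero; round-then-average is available behind
`average_first = FALSE`.

## SAD events and rates

A **SAD event** is a pathologist-year whose signing-week count drops by
*more than* 13 ISO weeks (a quarter year) versus the prior year, excluding
years whose prior year was itself an event — otherwise a departure straddling
December would be counted twice. Events are resolved in ascending year
order; a signer who vanishes entirely counts as 0 current weeks; new hires
have no prior year and cannot generate a first-year event; the first study
year yields none. The 13-week threshold is exposed (`drop_weeks`) for
sensitivity analysis.

The **SAD rate** divides events by FTEs: per group-year, as the arithmetic
mean of yearly rates over the period, and cumulatively for the whole
laboratory as total events over the *mean* yearly lab FTE (the alternative
sum-of-FTE-years denominator is behind a flag). `rescale_period()`
pro-rates a cumulative rate linearly to another period length, e.g. a
cumulative 100% over 8 years is 37.5% over 3 years — the form used when
comparing against published 3-year turnover surveys.

## The synthetic laboratory

Real sign-out extracts are rarely shareable, so the generator is first-class:
it emulates the *structure* of a regional laboratory and writes a
`TruthLedger` sufficient to predict every downstream quantity.

* **Activity.** Each pathologist-year signs in a known set of ISO weeks,
  sampled from weeks 2–50 so that ISO and calendar years coincide and the
  ledgered week count is recovered exactly. An uninterrupted year has 46
  signing weeks (hence FTE 1). Scheduled drops keep only the earliest
  `residual_weeks`; departures end the career; hires start at a given week,
  giving partial first years.
* **Workload.** A member's pro-rata units are drawn from a gamma
  distribution with the group mean and CV = `dispersion` (lognormal behind a
  flag; the choice of a positive, right-skewed family is ours — no
  distribution is implied by sign-out data). Draws use stratified
  (jittered-quantile) sampling across the group-year: with n ≈ 10 members an
  iid sample's Gini is noisy, while stratification concentrates the realized
  Gini near the calibrated value, which is the point of a generator
  advertised as "dispersion tunable to a target Gini".
  `calibrate_dispersion()` bisects the CV until the mean simulated
  bias-corrected Gini at the target group size is within ±0.01 of the
  target.
* **Cases.** Case volume scales with the member's drawn workload (heavier
  signers see more cases). Every case carries its rule's base units; the
  remainder of the annual draw is spread over cases by exponential weights
  and realized as integer block/specimen counts via largest-remainder
  apportionment. Integer counts quantize each annual total to the tariff
  grid (within one tariff step per case class), so the ledger records the
  *realized* totals — those are recovered by the pipeline at machine
  precision.
* **Exclusions.** A configurable rate of review / external-referral cases is
  injected into already-active weeks (so they never alter week counts) and
  ledgered, exercising the exclusion audit trail.

Two scenarios ship with the package. `paperlike_small` (3 groups × 4
pathologists × 4 years, ~13k cases) runs in well under a second and powers
most tests. `paperlike_full` emulates a 9-year regional laboratory: rosters
of 10/10/11 full-time pathologists (~31 FTEs), per-FTE means
8100/6900/4200, dispersions calibrated to Ginis 0.05/0.16/0.23, 30 scheduled
drops (to 20 residual weeks) over the final 8 years allocated 10/13/7 across
groups with about a third being departures replaced by partial-year hires,
and ~44 cases per signing week (~525k reports); it generates and analyzes in
under half a minute on one CPU.

What passing tests on synthetic data do and do not show: they demonstrate
that scoring, aggregation, grouping, inequality and event detection are
mutually consistent and recover known truth under realistic sample sizes.
They cannot show that real laboratories satisfy the generator's assumptions —
independent yearly draws, stable case-mix per group, single-site loyalty of
signers, no mid-week site switching, gamma-shaped dispersion — so estimates
on real extracts inherit none of the generator's guarantees.

## Numerical choices and degenerate inputs

* Gini needs n ≥ 2 and a nonzero total: otherwise `NA` with a warning, never
  a silent 0. Negative values are a domain error. Results are never clipped.
* Lorenz of an all-zero vector returns the diagonal with a warning.
* Group summaries of a single member report `sd = NA`, never 0; period
  averages drop missing yearly values column-wise.
* Group-assignment ties go to beta (outer) and beta2 (inner) — the rule's
  else-branches.
* Robin Hood integers round half *away from zero* (commercial rounding), not
  banker's rounding, and the rounding residual goes to the largest absolute
  adjustment.
* Malformed ingest rows are rejected with row numbers and reasons, and
  exclusion removals are counted per class and year: `n_in = n_out +
  rejected + removed` always holds.

## Known limitations

* Consult and ancillary work by non-finalizing pathologists is credited to
  the finalizing signature, understating some members' effort.
* The FTE rule cannot distinguish vacation-heavy full-timers from true
  part-timers near the 41/42-week boundary, and SAD events cannot
  distinguish absence from departure — by design, since only sign-out data
  are used.
* The bundled tariff is illustrative; absolute unit levels are only
  meaningful under a real schema supplied by the user.
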