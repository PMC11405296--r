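---
title: "Methods: disproportionality signal detection and onset modelling for FAERS reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signal detection and onset modelling for FAERS reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous reporting systems such as FAERS collect suspected drug–event
reports with no denominator of exposed patients, so incidence cannot be
estimated. What can be estimated is *disproportionality*: whether an event
is reported with a target drug more often than the reporting background
would predict. This package implements that analysis end to end for
anti-BCMA CAR-T cell products (and, by configuration, any drug): ingestion
and deduplication of the quarterly files, cohort selection by suspect
role, 2×2 contingency construction, ROR and IC statistics with signal
criteria, stratified and subset analyses, and Weibull time-to-onset
modelling. A signal here is a hypothesis generator, never evidence of
causality.

## Ingestion and deduplication

FAERS quarterly files are "$"-delimited ASCII with one header row. The
parser keeps rows in source order, coerces rows whose field count
disagrees with the header (padding or truncating) while counting them,
and tolerates the common trailing-"$" artifact as an empty final field
with a logged count. Nothing is silently dropped. Column-name dialects
(`PRIMARY_ID` vs `PRIMARYID`, `GNDR_COD` vs `SEX`) are normalized through
a single alias map; the pre-2012Q4 ISR-keyed legacy format is out of
scope.

**Partial dates.** FAERS dates may be `YYYY`, `YYYYMM`, or `YYYYMMDD`.
Year-only dates impute to July 1 and year-month dates to the 15th, and
both carry an `imprecise` flag. Midpoint imputation is unbiased for
interval statistics, and the flag lets the time-to-onset analysis exclude
imputed dates entirely (its default).

**Deduplication.** Multiple records of the same case share a `CASEID`.
Following the FDA-recommended rule, the record with the most recent
`FDA_DT` is kept; ties are broken by the higher `PRIMARYID`. Two details
make the rule total and deterministic: an unknown `FDA_DT` sorts earliest
(a dated version of the case always wins over an undated one), and id
comparison is numeric for ids that parse as numbers with a lexicographic
fallback — compared as one total order (numeric-parseable ids rank above
non-parseable ones at equal date) because a pairwise "numeric if both
parse" rule is not transitive for mixed id sets. Quarters are concatenated
*before* deduplication, since duplicate chains cross quarter boundaries.
The operation is idempotent, conserves counts (kept + removed = input),
and is invariant to input order; the test suite checks all three.

**Demographic typing.** `AGE`/`AGE_COD` converts to years (`DEC`×10,
`MON`/12, `WK`, `DY`, `HR`), `WT`/`WT_COD` to kilograms, occupation codes
to healthcare professional (`MD`, `PH`, `OT`, `HP`, `RN`) versus consumer
(`CN`, `CSM`) versus unknown. FAERS outcome codes are multi-valued per
report; for the characteristics table each report is reduced to one
category by severity priority death > life-threatening > hospitalization >
disability, with the remaining codes (congenital anomaly, required
intervention, other) folding into *Other*. Published characteristics
tables for these products sum outcome rows to the cohort size, which is
only possible under some such reduction; the priority order is the
conservative one (the most serious outcome wins). Percentages are rounded
half-up to one decimal, the convention of published tables.

## Cohorts and the MedDRA hierarchy

A cohort is defined by a pattern list (brand, generic, development code
names) matched case-insensitively as substrings of the normalized verbatim
drug name, restricted to primary/secondary-suspect roles by default.
Pattern lists are configuration with shipped defaults for the two CAR-T
products, because verbatim FAERS drug strings are noisy and no external
vocabulary normalization is attempted. Cohort selection is monotone in the
pattern list (adding a pattern can only grow the cohort), a property the
suite tests.

MedDRA is licensed, so the package ships no dictionary: SOC-level analysis
requires a user-supplied PT→SOC table, and the synthetic generator emits
its own consistent mini-dictionary so that tests are self-contained.
Unmapped PTs are retained for PT-level analysis and reported as a
fraction; above 50% unmapped triggers a warning, since that usually means
a wrong dictionary version.

## Disproportionality statistics

The counting unit is the (report, term) pair: a report mentioning a PT
twice counts once, and at SOC level a report counts once per distinct SOC.
The comparator ("universe") for `c` and `d` is the full deduplicated
report set in the analysis stratum — all other drugs, not a chosen
comparator set.

* **ROR** = (a·d)/(b·c), 95% Wald interval on the log scale with
  z = `qnorm(0.975)`. Any zero cell leaves the ROR undefined with a reason
  code; Haldane's +0.5 correction is available behind a flag but off by
  default, because silently inventing interval mass for sparse events is
  exactly what the IC path is there to avoid.
* **IC** uses the closed-form shrinkage variant: E = (a+b)(a+c)/N,
  IC = log₂((a+½)/(E+½)),
  IC025 = IC − 3.3(a+½)^−½ − 2(a+½)^−3/2. This is the dominant modern
  formulation; a report-level credibility analysis with a full gamma
  posterior would change IC025 by O(1/a) here and is not implemented.
  Note that a *constant* IC − IC025 gap across events of very different
  case counts is not producible by any count-based credibility interval;
  published tables showing one were likely produced by a different (and
  unstated) convention, which is one reason the acceptance checks validate
  formulas against enumeration rather than against printed IC025 columns.
* **Signal criteria** default to n ≥ 3 with ROR CI lower bound > 1, and
  IC025 > 0; both configurable. No multiple-testing correction is applied
  — deliberately, matching pharmacovigilance screening practice where the
  cost asymmetry favours sensitivity; users comparing hundreds of PTs
  should treat the flag count accordingly.

Rankings ("top 20 by ROR") order signal-positive events by the chosen
statistic with ties broken by case count then name. Signals absent from a
supplied product-label term list are flagged *unexpected*; an empty label
list flags every signal, with a warning. A small audit utility
(`ror_ci_feasible()`) checks a published (n, CI) pair for Wald-width
feasibility: log(hi/lo)/(2z) can never be below √(1/a).

## Stratified and subset analyses

Subgroup scans rebuild the contingency tables *within* each stratum
(female, male, 18–64, ≥65 by default): both cohort and comparator are
restricted before counting, so stratum tables are genuine conditional
analyses, not post-hoc splits. Reports with unknown sex or age are
excluded from the corresponding strata but retained overall; the under-18
stratum is omitted by default because report counts in this therapeutic
area are negligible. Sex-difference signals use the within-cohort
female-vs-male ROR (rows sex, columns event), the standard
sex-disproportionality construction; it inverts exactly under swapping the
sexes. The death-outcome analysis restricts both cohort and universe to
reports whose outcome codes include death and recomputes the full scan.
The malignancy screen aggregates term groups (HLGT-style) into composite
events and leans on the IC, which stays defined at zero counts; the
shipped group file carries illustrative, clearly synthetic PT memberships
to be replaced by the user's licensed hierarchy.

## Time to onset and the Weibull model

TTO is the event date minus the *earliest* start date among drug entries
matching the query, in whole days. Every (report, event) record carries a
validity code (`valid`, `negative`, `missing_start`, `missing_event`,
`imprecise_date`); only valid records enter summaries and fits, and
midpoint-imputed dates are excluded by default.

The two-parameter Weibull is fitted by maximum likelihood over
log-parameters (BFGS with analytic gradient) from a moment-based start
(shape from the SD of log-times via the Gumbel relation). Convergence
requires the gradient norm at the optimum to be numerically zero; the
observed information matrix gives Wald CIs on the log scale, so bounds are
always positive — matching the symmetric printed style of published fits.
Profile-likelihood intervals were considered and not implemented: at the
sample sizes involved (hundreds of onsets) the log-parameter likelihood is
close to quadratic and the two constructions agree to well within the CI
width. Failure-type classification is a total function of the shape CI:
*early* if the CI lies below 1, *wear-out* above 1, *random* if it
contains 1, *indeterminate* for failed fits.

**Day-0 onsets.** Weibull support is t > 0, but same-day onsets dominate
CAR-T reporting (infusion-reaction physiology). The default shifts 0 to
0.5 day — the midpoint of the day-0 interval — keeping that mass in the
fit; dropping zeros or offsetting all records by one day are available
alternatives. Published analyses rarely state their handling; the choice
noticeably affects the scale, mildly affects the shape, and never affects
the early/random/wear-out call at these sample sizes.

Fits refuse degenerate inputs explicitly (fewer than 10 usable records,
or all values equal) rather than erroring. An independent implementation
(`fitdistrplus`) is used in the test suite as a cross-check of estimates
and log-likelihood; it is never on the analysis path.

## The synthetic generator and what passing tests mean

`simulate_faers()` emits the same file dialect the parser reads (the
round-trip is itself a test) with: a multi-drug, multi-PT background;
configurable target-drug shares; implanted (drug, PT) signals with known
relative reporting rate, optionally restricted to a stratum; duplicate
chains (shared CASEID, strictly earlier FDA_DT, higher PRIMARYID — so the
dedup rule must keep exactly the originals); demographics drawn from
configurable categorical tables; and onset times drawn per implant.

The generative model is chosen for exact auditability. Background PT
multiplicity is K ~ max(1, Poisson(λ = 1.7)) per report — resembling
spontaneous-report multiplicity — with PT slots drawn with replacement and
de-duplicated, giving the *exact* closed-form per-report inclusion
probability p0 = E[1 − (1 − 1/n_PT)^K] used by `expected_contingency()`.
An implant replaces the background presence of its PT on eligible reports
with an independent Bernoulli(rate·p0), so P(PT | target drug) is exact by
construction and the expected ROR is (p·(1−p0))/((1−p)·p0) with
p = rate·p0. Infeasible configurations (rate·p0 > 0.95) are rejected
before generation.

Defaults encode the study conditions this package was built around:
reports uniform over 2019–2023, a ~10% death-outcome rate, male
predominance with a large unknown fraction, 5% duplicate chains, and
baseline onsets from Weibull(shape 0.43, scale 12.67 days) — the
early-failure regime reported for these products, under which the
closed-form 30-day onset fraction is 1 − exp(−(30/12.67)^0.43) ≈ 0.765.
Real reporting distributions are *not* pure Weibull — they carry a day-0
spike far above any Weibull density, so an empirical ≤30-day share can
exceed the fitted CDF by several points; tests therefore compare simulated
proportions against the generator's own CDF, the quantity that is actually
identified. Late-onset malignancy implants default to Weibull(shape 2,
scale 400 days).

What the generator does *not* emulate: drug-name noise beyond exact
strings (no misspellings), correlated event co-reporting (PTs are
conditionally independent given the drug), reporting-rate drift over
calendar time, and E2B/XML ingestion. Passing tests therefore demonstrate
the statistical machinery and plumbing are correct under a known model;
they say nothing about dictionary quality or drug-string recall on real
FAERS data.

## Calibration and recovery experiments (problem sizes)

The validation suite runs, per replicate, a 5,000-report universe with 5%
duplicates:

* **Null calibration** (100 seeds, no implants): the target cohort is
  given a 15% share (~750 reports) so that the n ≥ 3 case floor barely
  selects (E[a] ≈ 7; the analytic conditional inflation
  E[a | a ≥ 3]/E[a] is 1.02). Under that design the mean ROR across
  eligible PTs sits within 0.15 of 1, the median within 0.10, and the
  false-signal rate stays at or below 5%. With a small cohort
  (E[a] ≈ 2) the same statistic is structurally inflated to ≈ 1.7 purely
  by selection on the case floor — a property of conditioning, not a bug —
  which is why the calibration design pins E[a] well above the floor.
* **Recovery** (100 replicates): implanted rates 5, 10, 50 on the default
  5%-share cohort (expected a ≈ 11.7, 23, 117) are flagged by the default
  criteria with ≥95% sensitivity.
* **Weibull recovery** (200 replicates of n = 676 draws at shape 0.43,
  scale 12.67): the 95% Wald CI covers the true shape in ≥90% of
  replicates (observed ≈95%), and every fit whose CI upper bound is below
  1 classifies as early failure.

These sizes keep the full suite under two minutes on one CPU while leaving
all Monte Carlo margins wide.

## Known limitations

* Signal criteria and the IC formulation are conventions; other groups'
  thresholds (or PRR/EBGM estimators, for which hooks exist but which are
  not implemented) will flag different event sets.
* No censoring model: onsets are fitted as observed; events not yet
  reported are simply absent, which biases late-onset scales downward.
* Drug-name matching is substring-based; recall on real FAERS strings
  depends entirely on the supplied pattern list.
* The dedup rule trusts CASEID; split or re-keyed cases in real data
  remain distinct reports.
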