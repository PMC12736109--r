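---
title: "Disproportionality signal detection on spontaneous adverse-event reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection on spontaneous adverse-event reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faerspv)
```

## The problem

Spontaneous reporting systems such as the FDA Adverse Event Reporting
System (FAERS) collect millions of suspected drug-adverse-event reports.
They have no denominator — nobody knows how many patients took each drug —
so absolute risks cannot be estimated. What *can* be estimated is
disproportionality: whether an event is reported more often with a target
drug than with all other drugs, relative to each side's overall reporting
volume. `faerspv` implements this analysis end to end for FAERS-style
quarterly ASCII data, with the IL-1 inhibitor class (anakinra,
canakinumab, rilonacept) as its motivating use case: report assembly,
identifier-based deduplication, primary-suspect cohort selection,
four-algorithm scans at the MedDRA preferred-term (PT) and system-organ-class
(SOC) level, demographic and reporter-type subgroup scans, and
time-to-onset analysis.

## From raw tables to analyzable cases

A FAERS quarter ships as "$"-delimited tables keyed by `PRIMARYID`
(report version) and `CASEID` (patient case): DEMO (demographics and
dates), DRUG (one row per reported drug with a role code), REAC (one row
per reported PT) and THER (therapy start/end dates). `assemble_cases()`
joins these into one record per report. Two normalization layers replace
the licensed dictionaries a production system would license:

* a user-supplied two-column PT-to-SOC table (the MedDRA stand-in), and
* a drug-synonym table mapping raw `DRUGNAME`/`PROD_AI` strings to a
  normalized ingredient (the RxNorm stand-in). Matching is exact after
  upper-casing and trimming — no fuzzy matching, so cohort membership is
  deterministic.

Because the same case is often submitted several times, counting raw rows
would double-count patients. `deduplicate()` keeps one row per `CASEID`:
the most recent `FDA_DT`, ties broken by the higher `PRIMARYID`. The rule
is idempotent and order-invariant, and the package deduplicates globally
across all loaded quarters (the stricter reading when a study spans many
quarters). A report with a missing receipt date never beats a dated
version; such rows are flagged in the audit.

## The four algorithms

Every scan is built on the case-level 2×2 table for one (cohort, term)
pair: `a`/`b` are target-cohort reports with/without the term, `c`/`d` the
same among all other deduplicated reports. A case contributes at most one
count per term regardless of how many times the term is listed
(switchable to raw pair counting as a sensitivity check). With
`N = a+b+c+d`:

* **ROR** `= ad/bc`, Woolf interval
  `exp(ln ROR ± 1.96·sqrt(1/a+1/b+1/c+1/d))`;
* **PRR** `= (a/(a+b)) / (c/(c+d))` with its delta-method interval and
  the uncorrected chi-squared statistic
  `(ad−bc)² N / ((a+b)(c+d)(a+c)(b+d))`;
* **BCPNN information component** `IC = log2(aN/((a+b)(a+c)))`;
* **MGPS relative reporting ratio** `EBGM = aN/((a+c)(a+b))` with
  `EBGM05 = exp(ln EBGM − 1.96·SE)`.

In this formulation `IC = log2(EBGM)` holds exactly, and the test suite
asserts it as an identity. A term is a *signal* only when all four
criteria hold simultaneously: `ROR` and `PRR` lower bounds above 1 with at
least 3 reports, `IC025 > 0`, `EBGM05 > 0`. The joint rule is therefore
never less conservative than any single criterion.

Three numerical choices deserve attention:

* **IC025.** The interval for the information component is the
  delta-method bound on the log2 scale,
  `IC − 1.96·sqrt(1/a+1/b+1/c+1/d)/ln 2`. This reproduces the spacing of
  published (IC, IC025) pairs given the corresponding (EBGM, EBGM05)
  spacing, and is well defined for negative IC, which an exponential-form
  expression would not be.
* **EBGM is unshrunk.** The MGPS column here is the observed-to-expected
  ratio itself, not DuMouchel's gamma-mixture posterior mean; full
  empirical-Bayes shrinkage is deliberately out of scope. A consequence
  of the paired `EBGM05 > 0` criterion is that the MGPS flag is satisfied
  by *any* table with all four cells positive — the exponential of a real
  number is positive. The criterion is implemented as published, and the
  threshold is exposed (`ebgm05_min`; set it to 2 for the conventional
  `EBGM05 ≥ 2` rule).
* **Zero cells.** When `b`, `c` or `d` is zero (with `a > 0`) a
  Haldane–Anscombe 0.5 correction is applied to all four cells for the
  ROR/PRR *interval* computation only; point estimates are left alone,
  and `a = 0` terms are never reported. The Bayesian bounds use the raw
  cells, so a saturated stratum (`b = 0`) correctly refuses to produce an
  IC025.

No multiple-testing correction is applied — a signal is the joint
threshold rule, as is conventional in this literature — but every scan
records how many terms it examined.

## Subgroups

`stratify_and_scan()` restricts *both* the target cohort and the
comparator to one stratum before rebuilding the tables: sex (F/M), age
band (`<18`, `18–65` with both boundaries included, `>65`), or reporter
group. Cases with a missing stratum variable are excluded, not imputed.
The healthcare-professional group defaults to all professional codes
(HP, MD, OT, PH, RN) versus consumers (CN); lawyers and missing
occupations enter neither group. A strict HP/MD-only variant is a flag,
since published analyses do not always state which minor professional
codes they folded in. Within-stratum comparators are used throughout: a
cross-stratum comparator would reintroduce exactly the confounding the
stratification is meant to remove.

## Time to onset

For each cohort report, onset time is the event date minus the earliest
therapy start among the report's primary-suspect drug rows; negative
differences and missing dates are excluded and audited. FAERS therapy
dates are frequently month-precision; these are imputed to day 15 at
parse time and flagged per observation rather than dropped, which would
otherwise discard a large share of records. One observation per case is
produced, consistent with case-level counting. Onsets are binned into
0–30, 31–60, 61–90, 91–120, 121–180, 181–360 and >360 days (closed on
the right; edges configurable).

Cumulative incidence curves per drug are computed over the pooled event
grid. Spontaneous reports carry no censoring information, so by default
every observation is an event and each curve is the group's empirical
CDF; a competing-event generalization (Aalen–Johansen via
`cmprsk::cuminc`) is available but off by default, since it is not known
what, if anything, should be treated as competing in this data. Groups
are compared with Gray's K-sample test (`rho = 0`). The reported
statistic and asymptotic p-value come from `cmprsk`. For small samples
`grays_test(..., permutations = )` adds a permutation p-value: group
labels are permuted and a weight-1 K-sample score statistic — the sum of
squared observed-minus-expected event counts over the at-risk sets, the
same functional applied to the observed and every permuted labelling —
is recomputed; the permutation test is valid for any fixed statistic,
and this one is cheap enough to evaluate a thousand times per call.

## The synthetic-report generator

`simulate_faers()` exists so every stage is testable without a
multi-gigabyte download. Its defaults are fixed study conditions, not
tuning knobs:

* three target drugs plus five comparator drugs; one primary-suspect
  drug per case;
* a ≥1-truncated Poisson number of PTs per case (mean 2.5) drawn from a
  ~60-term, 14-SOC background multinomial whose names mirror the events
  most reported for IL-1 inhibitors; planted (drug, PT, relative-risk)
  pairs multiply the background probability and renormalize;
* demographics with roughly half of ages and 7% of sexes missing, a
  62% female share among known sexes, and a consumer-heavy reporter mix
  — the missingness pattern typical of this database;
* a duplicate-report rate of 0.19, the removed-to-retained ratio of a
  full-database cleaning pass; duplicates are exact copies except for a
  later receipt date and higher version id, the minimal structure the
  deduplication rule acts on;
* per-drug onset laws reproducing the qualitative published pattern:
  anakinra lognormal(meanlog = log 45, sdlog = 2) (~42% within 30 days),
  canakinumab Weibull(shape 0.6, scale 450) (~42% beyond a year),
  rilonacept lognormal(meanlog = log 20, sdlog = 2.2) (~55% within 30
  days);
* receipt dates lag event dates by 0–90 days — enough to make annual
  counts meaningful without modelling reporting delay seriously.

The generator emits a ground-truth record (true drug, events, onset
days, duplicate links), and `oracle_counts()` provides an independently
coded brute-force recount used to validate the contingency module. What
the generator does *not* emulate — drug-name noise, indication fields,
polypharmacy correlation, notoriety-bias dynamics — bounds what passing
tests show about real data: they validate the statistical machinery and
the counting rules, not robustness to real-world name matching or
confounding by indication.

## Problem sizes and verification

The test suite validates the pipeline at the scales its design targets:
oracle equivalence on twenty random datasets of 1,000–20,000 cases; null
calibration (all relative risks 1) and planted-signal recovery (relative
risk 8 against a 0.01 background) on 20,000-case datasets across 200 and
100 seeds respectively; Gray's-test level on 200 replicates of two
300-observation groups with 999-resample permutation p-values, and its
power against a fourfold exponential rate ratio at 500 per group.
Deduplication bookkeeping is checked exactly over 50 random
configurations. `scripts/acceptance.R` reruns the full pipeline on one
freshly simulated 20,000-case dataset and writes the headline quantities
as JSON.

## Limitations

Disproportionality is not causality: signals inherit confounding by
indication, channeling and notoriety bias from the reporting process,
and this package makes no attempt to adjust for them. Deduplication
relies solely on case identifiers, as the source data permits. The MGPS
column is unshrunk, so small-count terms have wider true uncertainty
than EBGM05 suggests — the joint rule's frequentist components are the
binding constraint there. Onset analysis uses whatever dates reporters
supplied, with month-precision imputation; it is descriptive, not a
survival model.
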