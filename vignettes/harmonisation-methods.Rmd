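---
title: "Methods: retrospective harmonisation with harmonisr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: retrospective harmonisation with harmonisr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The harmonisation model

`harmonisr` implements *algorithmic* retrospective harmonisation: a
harmonised variable is a deterministic function of study-specific source
variables, defined per study-wave by a declarative rule. No statistical
calibration (latent-variable or regression-based alignment) is attempted —
the package's position is that categorical questionnaire constructs should
be harmonised by explicit, reviewable recodes, and that anything a recode
cannot express honestly should be a reasoned exclusion rather than a forced
match.

The unit of harmonisation is the **study-wave**: one study's data from one
measurement occasion. A `harmonisation_spec` declares the target categories
(always including a reserved `Missing`) and, for every contributing
study-wave, exactly one of:

* **category map** — a total function from declared source categories to
  target categories;
* **threshold bins** — ordered right-closed intervals over a non-negative
  continuous source;
* either of the above composed with a **source preference** order and/or an
  **inference rule**;
* a **wave exclusion** with a mandatory written reason.

Two structural invariants do most of the integrity work. *Conservation*:
for every included study-wave, category counts (including `Missing`) sum to
the number of participants — enforced when tabulating and again when a
report is assembled, so a dropped or duplicated participant cannot pass
silently. *Exclusion totality*: every study-wave carrying the construct's
variable-group tag in the dictionary must either be harmonised or carry a
reasoned exclusion; `validate_coverage()` reports violations as findings.

### Multi-resolution variables

Contributing studies differ in resolution, so a single harmonised variable
forces a choice between detail and coverage. The package's worked example
resolves this the standard way, by issuing several variants of one
construct: a five-category travel mode (`ICAD_SchoolTravel1`) for studies
with full mode detail, a binary active/other mode (`ICAD_SchoolTravel2`)
that every study-wave can feed — including walk/cycle-only instruments via
the inference rule — and a binned journey duration (`ICAD_SchoolTravel3`).
Consistency across resolutions is testable: collapsing the five-category
variable's output (`{Walk, Cycle} → Active`, the rest → `Other`) must
reproduce the binary variable's counts on shared study-waves, and the test
suite asserts exactly that.

## Numerical and semantic choices

**Bin boundaries.** Published processing rules are written for integer
minutes ("≤ 5", "6–15 inclusive", "> 15"), which leaves real-valued gaps
(5.5). Bins are therefore defined on the real line as right-closed intervals
`(-∞, u₁], (u₁, u₂], …, (u_k, ∞)` with strictly increasing bounds and an
unbounded last bin, so validation can guarantee that every non-negative
value lands in exactly one bin while integer data reproduce the printed
rule verbatim. A property test sweeps random rationals with ≤ 3 decimals to
confirm totality.

**Negative durations** are a validation error, not `Missing`: a negative
minute count indicates upstream corruption (or an untranslated missing
code) that should be fixed at source, and mapping it to `Missing` would
hide it from the recode audit.

**Label matching** is exact after Unicode NFC normalisation and whitespace
trimming. Translated instruments (German/French response options) are
harmonised by mapping their verbatim labels; no fuzzy matching is offered
because a near-miss ("Walkk") more often signals a dictionary error than a
legitimate variant, and silent miscoding is the costlier failure. The
unmapped-value policy defaults to `error` for the same reason; `missing` is
available per rule.

**Missing sentinel and native codes.** The canonical missing sentinel is
the empty CSV field. Studies that encode missingness as numeric codes
(9, −99) have those declared at table-load time
(`read_study_table(missing_codes = )`); translations are counted and
surfaced in the report's decision ledger rather than applied invisibly.
The dictionary CSV keeps a fixed canonical header, so these codes are
load-time metadata rather than a dictionary column.

**Source conflicts.** When simultaneous sources disagree (parent says
walk, child says car), the default is `prefer_first` — the spec's stated
preference order is taken at its word — with `missing_if_conflict`
available per rule. Either way conflicts are counted and reported, so the
choice is visible rather than buried.

**Inference trigger.** On walk/cycle-only instruments, answering
negatively to *every* active-mode indicator implies a non-active mode. A
missing indicator is a non-response, not a "no", so by default it does
*not* trigger the inference; `treat_missing_as_negative = TRUE` is
available where an instrument's skip logic justifies it.

**Multi-select responses.** Instruments allowing several modes to be
ticked are handled as ordered sources (one indicator column per mode,
resolved by preference order), with the active-dominates-other ordering
expressed in the spec rather than hard-coded.

**Determinism.** Harmonised output is canonically sorted by
(study, wave, participant, variable); identical inputs yield byte-identical
output regardless of input row order. Reports contain a single timestamp
header line and are otherwise byte-stable; each report records an md5
content hash of the canonical serialisation of every spec it documents, so
a report provably corresponds to a spec version.

## The synthetic generator

`generate_studies()` emulates the features of pooled questionnaire data
that the engine must survive: several studies with different instruments,
category schemes and labels, wave-prefixed wide tables, per-variable
missingness, and respondent heterogeneity. Its central design commitment is
**exact marginal reproduction**: a blueprint declaring category counts is
realised by deterministic allocation (repeat each category its declared
number of times, plus the declared missing count) followed by a seeded
permutation. Published marginal tables can therefore be converted into
participant-level test data whose harmonised counts must match the
published summaries *exactly*, not in expectation.

The packaged worked example applies this to three child cohorts at wave 1:

* **SPEEDY** (n = 2064, child-reported): four mode categories; journey
  durations estimated separately for walking and cycling only, so duration
  values are generated solely for walk/cycle participants, with the pooled
  bin counts (356 / 432 / 193, plus 22 item non-responses) fixed exactly
  and within-bin integer values weighted so that each item's quartiles land
  within one minute of the instrument summaries (p25 5, median 10, p75 15).
  Bin counts, not moments, are the reproduction surface: moments alone
  underdetermine participant-level values.
* **KISS** (n = 540, parent-reported, German instrument): summer-journey
  mode (the variable name carries no wave prefix, exercising the
  dictionary's wave-field path) and a free-text duration in minutes on
  1–30, with bin counts 153 / 249 / 50 and 88 missing fixed exactly. Only
  the summer item is modelled; how any winter items were treated is not
  recorded, so none are fabricated.
* **Ballabeina** (n = 669, parent-reported, French/German instrument):
  five mode categories and a *categorical* duration (`<10 / 10–20 / >20`
  min) whose boundaries are incompatible with the harmonised bins —
  included precisely so the reasoned-exclusion path is exercised end to
  end.

SPEEDY's travel-frequency item is catalogued in the dictionary but unused
by any spec, mirroring the common situation of catalogued-but-unharmonised
source variables. Sex and age columns give the dictionary's time-invariant,
non-construct entries.

What the generator does **not** emulate: correlated missingness between
items, within-family clustering, longitudinal consistency across waves,
measurement error or response biases, and free-text answers needing
cleaning. Passing tests on generated data therefore demonstrate the
*bookkeeping* correctness of the pipeline — exact recodes, conservation,
exclusion handling, provenance — not robustness to the messiness of real
field data, which is exactly the division of labour intended: the messy
part of harmonisation is the human judgement encoded in the specs, and the
package's job is to execute and document that judgement faithfully.

**Consortium coverage registry.** Study-level inclusion lists behind the
published per-variable coverage totals (11 studies / 21 waves, 14 / 25,
8 / 13) are not public; `school_travel_registry()` encodes the per-variable
histograms of studies by wave count using synthetic study ids
(`study01`…`study14`), documented as such, which is sufficient for
`coverage_summary()` to reproduce the totals.

## Parameters that matter

| Parameter | Where | Default | Why |
|---|---|---|---|
| `unmapped_policy` | category map | `error` | silent missingness hides recode gaps |
| `conflict_policy` | source preference | `prefer_first` | the stated preference order is authoritative; conflicts still counted |
| `treat_missing_as_negative` | inference rule | `FALSE` | a non-response is not a "no" |
| bin bounds | threshold bins | — (minutes) | right-closed; last bin unbounded; validated strictly increasing |
| `missing_codes` | table load | none | native numeric missing codes, translated and logged |
| `seed` | generator | fixture `1903` | output is a pure function of config; marginals are seed-invariant |

## Problem sizes

The test suite runs the full three-study example (3273 participants),
100 randomly generated study-waves of up to 500 participants for
conservation, 1000-row instances for each transform's brute-force oracle
comparison, and 500-point sweeps for bin totality — sizes chosen so the
whole suite exercises every code path in well under a minute on one core
while keeping counting arguments exhaustive where they matter.

## Known limitations

* One variable group per dictionary entry: multi-group tagging is not
  supported, so a variable serving two constructs must be duplicated under
  a second name.
* No statistical calibration of continuous instruments; constructs that
  cannot be aligned by recode or binning must be excluded with a reason.
* Respondent-only source selectors require the dictionary to resolve to
  exactly one column per study-wave; ambiguous cases must name variables
  explicitly.
* The wide-table convention assumes participant linkage across waves is
  already encoded in the master file; no record linkage is attempted.
* Reports mirror the in-package table layouts; no PDF or web output.
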