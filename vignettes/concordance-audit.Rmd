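---
title: "Auditing EGFR/proteomic testing and erlotinib decisions: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing EGFR/proteomic testing and erlotinib decisions: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsaudit)
```

## The clinical decision model

In advanced non-small cell lung cancer, the recommended workup when an
EGFR tyrosine kinase inhibitor is under consideration is strictly ordered:
EGFR mutation testing comes first (squamous histology is exempt, since
activating mutations are rare there); for EGFR-negative or EGFR-unknown
patients the serum proteomic test is the companion step, its "Good"/"Poor"
call indicating whether the patient stands to benefit more from the TKI or
from platinum-based chemotherapy; and the erlotinib decision should follow,
informed by that result. An audit of concordance therefore has to look at
*timing*, not just agreement between final result and final prescription:
a "Good" patient on erlotinib looks concordant in a cross-sectional tally
even when the drug was started weeks before the result existed.

`vsaudit` models each patient as a single row of events (one proteomic
test, at most one EGFR test, at most one erlotinib course — repeated events
are out of scope because no patient in the audited setting had them) and
extracts exactly two decisions per patient, a convention chosen because the
audited decision count is exactly twice the cohort size:

1. the **testing-sequence decision** (rules T1–T5), and
2. the **treatment decision** (rules X1–X6).

Rules are evaluated first-match in a fixed order, so a timing violation
(X1) dominates result agreement (X2–X4): a pre-result start is a departure
regardless of what the result later said. Every valid record matches some
rule in each family — the rule set is exhaustive by construction, which the
test suite verifies against an independently written lookup oracle over all
84 realizable attribute combinations.

Dates are calendar dates at day resolution; the audited timelines are
reported at day/week granularity and intra-day ordering is not modelled.

### Conventions the rule set had to fix

A few points are genuinely underdetermined by the audit design we follow,
and the package fixes them as explicit policy:

* **T2 as the complement of T1.** "EGFR performed" splits into result
  available on/before the proteomic order (T1, green) and result arriving
  after it (T2, red). An earlier formulation — red only when the EGFR
  result postdates the proteomic *result* — leaves records with an EGFR
  result arriving between the proteomic order and result unclassifiable.
  The package codes any proteomic order placed before the EGFR result was
  available as the departure: the testing sequence, not the paperwork lag,
  is what the rule is about.
* **Timing reference for X1** (`decision_policy(timing_reference=)`).
  Whether "erlotinib before the proteomic test" should compare the drug
  start to the test's *order* date or its *result* date is not fixed by the
  audit narrative. The default is the result date, because a result that
  does not exist yet cannot inform a prescription — this makes a same-day
  order of drug and test (case scenario S3) a departure, which is how that
  scenario is characterized. The order-date convention is available as a
  policy switch.
* **End-of-life window**: "within 3 months of death" is implemented as 90
  days, inclusive at both ends (a test on the death day counts, and so
  does one exactly 90 days before). It is measured from the proteomic
  *order* date — the day the decision to test was made — rather than the
  result date; this too is a convention, exposed via
  `decision_policy(eol_window_days=)`.
* **Mixed adeno-squamous histology** is treated as non-squamous for the
  testing rules (the exemption is for purely squamous disease).

### The end-of-life exception (X5)

The published decision tallies this package reconstructs are internally
inconsistent by two decisions: the narrative yellow counts sum to 26
(4 + 13 + 8 + 1), while the summary states 24, alongside 105 green and 9
red. The package resolves this by treating the summary totals as
authoritative and introducing a documented exception: a "Good" result with
no erlotinib is *green* rather than yellow when the patient died within the
end-of-life window of the test order **and** the chart documents a
justification. Exactly two fixture patients carry that combination. The
exception is a package design choice, not a rule stated by the audit it
reconstructs; it ships enabled, and disabling it
(`decision_policy(eol_exception_enabled = FALSE)`, or `--no-eol-exception`
on the CLI) recovers the narrative arithmetic of 103/26/9. The toggle
provably changes nothing else: a property test checks that the only code
movements are yellow↔green on X5-eligible records.

## The fixture cohort

`build_fixture_cohort()` returns a deterministic 69-patient cohort whose
every published marginal is reproduced exactly. Three pathway groups:

* **Group A (28)** — EGFR negative with the result before the proteomic
  order: 17 "Good" treated after the result, 4 "Good" untreated, 6 "Poor"
  untreated, 1 "Good" with a pre-result erlotinib start.
* **Group B (36)** — EGFR never performed (17 squamous, 6 without usable
  tissue, 13 non-squamous undocumented): 15 "Good" treated after the
  result, 10 "Poor" untreated, 8 "Good" untreated, 1 "Poor" treated after
  the result, and 2 pre-result starts (one "Good", one "Poor" — the
  "Poor" assignment is forced by the printed total of exactly 2 treated
  "Poor" patients).
* **Group C (5)** — proteomic test first, EGFR (negative) only later:
  3 "Good" treated, 1 "Poor" untreated, 1 "Good" untreated. This split is
  not printed directly; it is solved from the printed marginals (50
  "Good", 19 "Poor", 37 treated "Good"). Any alternative satisfying all
  marginals would be acceptable; the shipped composition is frozen.

The joint assignment of Group B's no-test reasons to its outcome leaves is
likewise not printed; the fixture zips the two printed distributions
positionally and freezes the result.

Nine patients die 60 days after their proteomic order (within the 90-day
window): two untreated "Poor" from Group A, the two justified "Good"
patients and two untreated "Poor" from Group B, and the three treated
near-death patients (one "Good", two "Poor"). A tenth death falls 200 days
after the order, outside the window.

Demographics reproduce the published profile: race 48/12/9
white/black/other; 11 care networks with counts 13/12/12/10 for the top
four (68% of tests) plus 22 spread over seven more; histology 39 adeno /
20 squamous / 1 mixed / 1 large-cell neuroendocrine / 8 unspecified. The
age list is a frozen 69-integer vector found by constraint search so that
the decade bands count 7/31/24/7, the range is 50–89, the mean rounds to
69.2 and the sample standard deviation to 8.5. Diagnosis dates stagger
weekly from 2013-01-01 with fixed per-group event gaps, so the whole
cohort is reproducible byte for byte.

Reported race percentages in the source table imply a denominator smaller
than the cohort (48 "White" printed as 76% implies 63, not 69); the
fixture stores counts and the summary computes percentages over the full
cohort.

### Case scenarios

`build_scenario_records()` ships the four published timing-departure
timelines as a separate 4-record file (S1–S4) rather than force-mapping
them onto fixture patients, because the narrative counts cannot be
reconciled with all four scenarios simultaneously — it is ambiguous
whether the "2 patients treated despite Poor status" include those whose
"Poor" result only arrived after the start. S1's erlotinib exposure is 63
days dispensed against a 3 months' supply; under 30-day block billing both
readings price identically. S3's supply duration is never printed; the
record carries the minimal one month (30 days) so that the invariant
"start date implies days supplied" holds, and no cost assertion is made
for S3 anywhere in the package.

## The cost model

Unit costs default to the published figures: \$500 (EGFR test), \$2,112
(proteomic test), \$4,815 (erlotinib, 100 mg, one month's supply).
Erlotinib is billed in 30-day blocks rounded up, since only a monthly
price is published; dose does not change cost. The *non-concordant spend*
attribution — a red testing decision attributes the proteomic test cost, a
red treatment decision attributes the erlotinib supply cost — is this
package's operationalization of the qualitative argument that departures
produce excess cost with no documented benefit; it is a convention, and
all unit costs are overridable via the config file.

## The simulator

`simulate_cohort()` draws each patient's pathway leaf from the 13-leaf
distribution calibrated to the fixture proportions, then demographics and
event dates from configurable distributions (uniform integer-day gap
ranges; ages uniform within decade bands). Every generated record
satisfies the data-model invariants by construction, and a fixed
parameter set and seed reproduce the cohort exactly. A goodness-of-fit
test (chi-square over leaf counts, α = 0.01, n = 12,000 in the unit suite
and 10,000 in the end-to-end suite) checks convergence to the configured
probabilities.

What the simulator deliberately does **not** emulate: correlation between
demographics and pathway (leaves are drawn independently of age, race and
site); repeated tests or multiple erlotinib courses; survival-time
structure beyond the near-death/late-death flags (defaults 9/69 and 1/69);
patients outside the proteomic-tested cohort; and secular trends in test
uptake. Passing property tests therefore demonstrate the engine's
correctness and the pipeline's invariants on schema-conformant data, not
calibration to any real EHR population.

Two simulator conventions are fixed once: simulated near-death "Good"
untreated patients always carry a documented justification (mirroring the
fixture, where the only such patients are the two justified ones), and
no-tissue patients get "unspecified" histology while undocumented-reason
patients draw adeno/mixed/large-cell at 0.8/0.1/0.1.

## Numerical and degenerate-input choices

* Percentages are integers rounded half-up (`round()`'s banker's rounding
  would turn 6.52% into 6%, not the published 7%); the half-up convention
  reproduces the printed 76/17/7 from 105/24/9 of 138.
* The age dispersion is the sample (n−1) standard deviation, the
  conventional choice where the source does not specify.
* `days_between()` is signed; the end-of-life check requires the test
  on or before the death day (a death *before* the test order never counts
  as near-death testing).
* Records with error-severity invariant violations (impossible orderings,
  orphan supply fields, malformed dates) are excluded at ingest with
  per-patient issues; an empty usable cohort is a hard error, as is a
  cohort summarized with zero rows.
* An EGFR-*positive* record is a policy error rather than a classifiable
  case: such patients proceed directly to the TKI and have no indication
  for proteomic testing, so their appearance in a proteomic-tested cohort
  means upstream data corruption.

## Problem sizes

The shipped suites run the fixture (69 patients, 138 decisions), the
84-row rule enumeration under both policy settings, simulated cohorts of
300–500 per seed for unit properties, and a single 10,000-patient cohort
(validation, classification, goodness-of-fit, cost properties) in the
end-to-end suite; these sizes give stable frequencies for the α = 0.01
goodness-of-fit check while keeping the whole suite interactive.

## Known limitations

* The two-decisions-per-patient unit and the X5 exception are
  reconstructions; the audited source defines neither explicitly.
* The fixture's within-group joint assignments (Group C, Group B's
  reason-by-outcome zip) are one consistent solution among several.
* Erlotinib exposure is a start date plus total days supplied; individual
  fills, dose changes and holds are not modelled (S1's hold appears only
  as the gap between start and the proteomic dates).
* Costs are opaque constants — no discounting, adverse-event or
  chemotherapy costs, and no distinction between acquisition and list
  prices.
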