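# vsaudit

Audit pipeline for biomarker test utilization and erlotinib prescribing in
non-small cell lung cancer (NSCLC).

Clinical guidelines sequence the workup of advanced NSCLC when an EGFR
tyrosine kinase inhibitor (erlotinib) is being considered: EGFR mutation
testing first (except in squamous histology, where activating mutations are
rare); then, for EGFR-negative or EGFR-unknown patients, the serum
proteomic test (VeriStrat), whose "Good"/"Poor" call predicts whether the
patient will benefit more from the TKI or from chemotherapy; and only then
the prescription, informed by the result. `vsaudit` is for health-services
and clinical-informatics researchers who want to audit how closely a
patient cohort's real-world event sequence followed that algorithm, and
what departures cost.

## The decision model

Each patient contributes exactly two audited decisions. A first-match rule
set codes each one **green** (concordant), **yellow** (questionable or
under-documented) or **red** (clear departure):

| Decision | Rule | Condition | Code |
|---|---|---|---|
| testing | T1 | EGFR negative, result available before the proteomic order | green |
| testing | T2 | EGFR performed, but only after the proteomic order | red |
| testing | T3 | EGFR skipped: squamous histology | green |
| testing | T4 | EGFR skipped: insufficient biopsy tissue | green |
| testing | T5 | EGFR skipped, non-squamous, reason undocumented | yellow |
| treatment | X1 | erlotinib started before the proteomic result | red |
| treatment | X2 | erlotinib despite a "Poor" result | red |
| treatment | X3 | "Good" result, erlotinib given | green |
| treatment | X4 | "Poor" result, no erlotinib | green |
| treatment | X5 | "Good", no erlotinib, documented end-of-life justification | green |
| treatment | X6 | "Good" result, no erlotinib, no justification | yellow |

Policy knobs (`decision_policy()`): the end-of-life window (90 days), the
X5 exception toggle, and whether X1 compares the drug start to the
proteomic *result* date (default) or *order* date. The cost model
(`cost_schedule()`) prices an EGFR test at \$500, the proteomic test at
\$2,112 and erlotinib at \$4,815 per 30-day supply, billed in 30-day blocks
rounded up; red decisions attribute their component's spend as
non-concordant cost.

The package ships a deterministic 69-patient fixture cohort that realizes
the full joint structure of a published utilization audit (EGFR status x
histology x tissue availability x proteomic result x erlotinib exposure x
event ordering), four case-scenario records with timing departures, and a
seeded stochastic cohort simulator for property testing.

## Worked example

```r
library(vsaudit)

cohort <- build_fixture_cohort()
decisions <- extract_decisions(cohort, decision_policy())
report <- build_report(cohort, decisions)
print(report)
#> Audit report: 69 patients, 138 clinical decisions
#>   green  105 (76%)  concordant with the testing algorithm
#>   yellow  24 (17%)  questionable or under-documented
#>   red      9 (7%)  clear departures
#>   pathway cost total: $523,353; attributable to red decisions: $34,635

print(summarize_cohort(cohort))
#> Utilization summary: 69 patients
#>   EGFR: negative 33, positive 0, not performed 36
#>   Proteomic: good 50, poor 19
#>   Erlotinib by result: good 37/50 treated, poor 2/19 treated
#>   Result-concordant (timing-agnostic): 54/69 (78%)
#>   Tested near death: 9 (3 treated, 2 of those poor)
#>   Age: mean 69.2 (SD 8.5); top-4 site share 68%
```

Of 138 decisions, 105 followed the recommended algorithm; 24 lacked
documentation (mostly missing EGFR tests in non-squamous disease, and
"Good" results never acted on); 9 were clear departures — proteomic tests
ordered before EGFR status was known, erlotinib started before the result
returned, or given against a "Poor" call. The timing-agnostic view (78%
result-concordant) overstates concordance because it cannot see those
ordering violations.

The same pipeline runs from a shell:

```sh
Rscript inst/cli/audit.R fixture --out work/
Rscript inst/cli/audit.R run --cohort work/cohort.csv \
    --report work/report.json --decisions work/decisions.csv
Rscript inst/cli/audit.R report --report work/report.json
Rscript inst/cli/audit.R simulate --n 200 --seed 7 --out work/sim.csv
```

`run` accepts `--config FILE` (flat `policy.*` / `costs.*` key-value
pairs), `--no-eol-exception`, `--eol-window N` and
`--timing-reference {result_date,order_date}`.

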