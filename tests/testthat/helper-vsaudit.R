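# Shared fixtures and the independent rule-classification oracle.

fixture_cohort <- build_fixture_cohort()
scenario_records <- build_scenario_records()

# ---------------------------------------------------------------------------
# Hand-written classification oracle.
#
# Written directly from the clinical narrative as a pair of decision trees
# over pathway attributes, independent of the engine's record-based
# first-match implementation. Attribute vocabulary matches
# enumerate_rule_table():
#   egfr: negative_before | negative_after | np_squamous | np_no_tissue |
#         np_undocumented
#   erlotinib: none | before_result | after_result
oracle_testing <- function(egfr) {
  switch(egfr,
    negative_before = c("green", "T1"),   # recommended sequence
    negative_after  = c("red", "T2"),     # proteomic ordered before EGFR known
    np_squamous     = c("green", "T3"),   # squamous exempt from EGFR testing
    np_no_tissue    = c("green", "T4"),   # serum test is the tissue fallback
    np_undocumented = c("yellow", "T5")   # unexplained missing EGFR test
  )
}

oracle_treatment <- function(vs, erlotinib, eol_justified) {
  if (erlotinib == "before_result") return(c("red", "X1"))
  if (vs == "poor") {
    if (erlotinib == "after_result") return(c("red", "X2"))
    return(c("green", "X4"))
  }
  # vs == "good"
  if (erlotinib == "after_result") return(c("green", "X3"))
  if (eol_justified) return(c("green", "X5"))
  c("yellow", "X6")
}

oracle_rule_table <- function(grid) {
  t_codes <- t(vapply(grid$egfr, oracle_testing, character(2)))
  x_codes <- t(mapply(oracle_treatment, grid$vs, grid$erlotinib,
                      grid$eol_justified))
  tibble::tibble(
    histology_class = grid$histology_class, egfr = grid$egfr, vs = grid$vs,
    erlotinib = grid$erlotinib, eol_justified = grid$eol_justified,
    testing_code = t_codes[, 1], testing_rule = t_codes[, 2],
    treatment_code = x_codes[, 1], treatment_rule = x_codes[, 2]
  )
}

expect_no_issues <- function(cohort) {
  issues <- validate_cohort(cohort)
  expect_identical(nrow(issues[issues$severity == "error", ]), 0L)
}

color_totals <- function(decisions) {
  as.integer(table(factor(decisions$code,
                          levels = c("green", "yellow", "red"))))
}
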