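# Rules engine: per-rule examples, oracle equivalence, policy properties.

test_that("testing rules classify the canonical pathway positions", {
  pol <- decision_policy()

  a <- classify_testing_decision(patient_record(), pol)  # negative before
  expect_identical(c(a$code, a$rule_id), c("green", "T1"))

  c_rec <- patient_record(egfr_result_date = "2013-05-15")  # after vs result
  cc <- classify_testing_decision(c_rec, pol)
  expect_identical(c(cc$code, cc$rule_id), c("red", "T2"))

  sq <- classify_testing_decision(
    patient_record(histology = "squamous", egfr_status = "not_performed",
                   egfr_result_date = NA, no_egfr_reason = "squamous"), pol)
  expect_identical(c(sq$code, sq$rule_id), c("green", "T3"))

  nt <- classify_testing_decision(
    patient_record(egfr_status = "not_performed", egfr_result_date = NA,
                   no_egfr_reason = "no_tissue", tissue_sufficient = "no"),
    pol)
  expect_identical(c(nt$code, nt$rule_id), c("green", "T4"))

  un <- classify_testing_decision(
    patient_record(egfr_status = "not_performed", egfr_result_date = NA,
                   no_egfr_reason = "undocumented"), pol)
  expect_identical(c(un$code, un$rule_id), c("yellow", "T5"))

  expect_error(
    classify_testing_decision(
      patient_record(egfr_status = "positive"), pol),
    "outside the proteomic testing pathway")
})

test_that("treatment rules classify result agreement and timing", {
  pol <- decision_policy()
  base <- function(...) patient_record(...)

  x3 <- classify_treatment_decision(
    base(erlotinib_start_date = "2013-03-29", erlotinib_days_supplied = 60L),
    pol)
  expect_identical(c(x3$code, x3$rule_id), c("green", "X3"))

  x2 <- classify_treatment_decision(
    base(vs_result = "poor", erlotinib_start_date = "2013-03-25",
         erlotinib_days_supplied = 30L), pol)
  expect_identical(c(x2$code, x2$rule_id), c("red", "X2"))

  # same-day order of drug and test: result cannot have informed it
  x1 <- classify_treatment_decision(
    base(erlotinib_start_date = "2013-03-01",
         erlotinib_days_supplied = 30L), pol)
  expect_identical(c(x1$code, x1$rule_id), c("red", "X1"))

  x6 <- classify_treatment_decision(base(), pol)
  expect_identical(c(x6$code, x6$rule_id), c("yellow", "X6"))

  x4 <- classify_treatment_decision(base(vs_result = "poor"), pol)
  expect_identical(c(x4$code, x4$rule_id), c("green", "X4"))

  eol <- base(death_date = "2013-04-30",
              treatment_justification_documented = TRUE)
  x5 <- classify_treatment_decision(eol, pol)
  expect_identical(c(x5$code, x5$rule_id), c("green", "X5"))
  off <- classify_treatment_decision(
    eol, decision_policy(eol_exception_enabled = FALSE))
  expect_identical(c(off$code, off$rule_id), c("yellow", "X6"))
})

test_that("timing reference policy switches the pre-result rule", {
  # started after the order but before the result
  rec <- patient_record(erlotinib_start_date = "2013-03-05",
                        erlotinib_days_supplied = 30L)
  by_result <- classify_treatment_decision(rec, decision_policy())
  expect_identical(by_result$rule_id, "X1")
  by_order <- classify_treatment_decision(
    rec, decision_policy(timing_reference = "order_date"))
  expect_identical(by_order$rule_id, "X3")
})

test_that("engine output equals the hand-written oracle on every combination", {
  table_default <- enumerate_rule_table(decision_policy())
  expect_identical(nrow(table_default), 84L)
  expect_true(all(table_default$testing_code %in%
                    c("green", "yellow", "red")))
  expect_true(all(table_default$treatment_code %in%
                    c("green", "yellow", "red")))
  expect_identical(as.data.frame(table_default),
                   as.data.frame(oracle_rule_table(table_default)))

  # spot-check the archetypal concordant row
  row <- table_default[table_default$egfr == "negative_before" &
                         table_default$vs == "good" &
                         table_default$erlotinib == "after_result" &
                         !table_default$eol_justified &
                         table_default$histology_class == "non_squamous", ]
  expect_identical(
    c(row$testing_code, row$testing_rule, row$treatment_code,
      row$treatment_rule),
    c("green", "T1", "green", "X3"))
})

test_that("extract_decisions yields exactly two decisions per patient", {
  decisions <- extract_decisions(fixture_cohort)
  expect_identical(nrow(decisions), 138L)
  counts <- table(decisions$patient_id, decisions$decision_kind)
  expect_true(all(counts == 1L))

  expect_identical(nrow(extract_decisions(fixture_cohort[0, ])), 0L)

  single <- extract_decisions(patient_record(
    erlotinib_start_date = "2013-03-29", erlotinib_days_supplied = 60L))
  expect_identical(single$rule_id, c("T1", "X3"))
  expect_identical(single$code, c("green", "green"))

  bad <- patient_record(age = 30L)
  expect_error(extract_decisions(bad), "invalid record")
})

test_that("decision extraction is deterministic and pure", {
  pol <- decision_policy()
  expect_identical(extract_decisions(fixture_cohort, pol),
                   extract_decisions(fixture_cohort, pol))
})

test_that("green result-agreement decisions imply timing-agnostic concordance", {
  sim <- simulate_cohort(simulation_params(400, seed = 13))
  decisions <- extract_decisions(sim)
  treatment <- decisions[decisions$decision_kind == "treatment", ]
  concordant <- result_only_concordant(sim)
  names(concordant) <- sim$patient_id
  agree_green <- treatment$rule_id %in% c("X3", "X4")
  expect_true(all(concordant[treatment$patient_id[agree_green]]))
  # and red treatment decisions are timing or result violations
  red <- treatment$rule_id[treatment$code == "red"]
  expect_true(all(red %in% c("X1", "X2")))
})

test_that("disabling the end-of-life exception only moves X5 records to yellow", {
  for (cohort in list(fixture_cohort,
                      simulate_cohort(simulation_params(400, seed = 21)))) {
    on <- extract_decisions(cohort, decision_policy())
    off <- extract_decisions(cohort,
                             decision_policy(eol_exception_enabled = FALSE))
    changed <- on$code != off$code
    expect_true(all(on$rule_id[changed] == "X5"))
    expect_true(all(off$code[changed] == "yellow"))
    expect_identical(on$code[!changed], off$code[!changed])
  }
})

test_that("result-only concordance ignores all timing", {
  pre_result <- patient_record(erlotinib_start_date = "2013-03-01",
                               erlotinib_days_supplied = 30L)
  expect_true(result_only_concordant(pre_result))
  expect_false(result_only_concordant(patient_record()))
  expect_true(result_only_concordant(patient_record(vs_result = "poor")))
})
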