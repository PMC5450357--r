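# Green/yellow/red rules engine for testing and treatment decisions.
#
# Each patient contributes exactly two audited decisions: the testing
# sequence (was EGFR testing done, documented or excusable before the
# proteomic test?) and the treatment decision (did erlotinib use follow the
# proteomic result?). Rules are evaluated first-match in a fixed order;
# rule IDs T1-T5 and X1-X6 are stable public identifiers.

#' Decision-classification policy
#'
#' Tunable conventions of the rules engine.
#'
#' @param eol_window_days End-of-life window in days (default 90, the
#'   day-resolution reading of "within 3 months of death"). Used both for the
#'   near-death testing metric and for the end-of-life treatment exception.
#' @param eol_exception_enabled When `TRUE` (default), a "good" proteomic
#'   result with no erlotinib is coded green rather than yellow if the
#'   patient died within the end-of-life window of the proteomic order and
#'   the chart documents a justification (rule X5). Disabling it reverts
#'   those decisions to yellow and never changes any other code.
#' @param timing_reference Which proteomic date erlotinib starts are compared
#'   against for the "drug before test" rule X1: `"result_date"` (default;
#'   a start on or after the order but before the result is still a
#'   departure, since the result could not have informed it) or
#'   `"order_date"`.
#'
#' @return A list of class `decision_policy`.
#' @export
decision_policy <- function(eol_window_days = 90L,
                            eol_exception_enabled = TRUE,
                            timing_reference = c("result_date", "order_date")) {
  timing_reference <- match.arg(timing_reference)
  eol_window_days <- as.integer(eol_window_days)
  if (is.na(eol_window_days) || eol_window_days <= 0L) {
    rlang::abort("eol_window_days must be a positive integer")
  }
  structure(
    list(eol_window_days = eol_window_days,
         eol_exception_enabled = isTRUE(eol_exception_enabled),
         timing_reference = timing_reference),
    class = "decision_policy"
  )
}

new_decision <- function(patient_id, decision_kind, code, rule_id, rationale) {
  tibble::new_tibble(
    list(patient_id = patient_id, decision_kind = decision_kind,
         code = code, rule_id = rule_id, rationale = rationale),
    nrow = length(patient_id))
}

#' Classify the testing-sequence decision for one patient
#'
#' First-match rules, in order:
#' \describe{
#'   \item{T1 (green)}{EGFR negative with the result available on or before
#'     the proteomic order: the recommended sequence.}
#'   \item{T2 (red)}{EGFR performed but its result postdates the proteomic
#'     order: the proteomic test was ordered before EGFR status was known,
#'     reversing the recommended sequence.}
#'   \item{T3 (green)}{EGFR not performed, squamous histology: EGFR mutations
#'     are rare in squamous tumors and guidelines exempt them.}
#'   \item{T4 (green)}{EGFR not performed for lack of biopsy tissue: the
#'     serum-based proteomic test is the intended fallback.}
#'   \item{T5 (yellow)}{EGFR not performed in non-squamous disease with no
#'     documented reason.}
#' }
#'
#' A record with a documented activating EGFR mutation
#' (`egfr_status = "positive"`) is a policy error: such patients proceed
#' directly to a TKI and have no indication for proteomic testing.
#'
#' @param record A one-row cohort tibble that passes [validate_record()].
#' @param policy A [decision_policy()].
#' @return A one-row decisions tibble (`patient_id`, `decision_kind`, `code`,
#'   `rule_id`, `rationale`).
#' @export
classify_testing_decision <- function(record, policy = decision_policy()) {
  stopifnot(nrow(record) == 1L)
  r <- as.list(record)
  if (identical(r$egfr_status, "positive")) {
    rlang::abort(paste0(
      "patient ", r$patient_id, ": EGFR-positive patients are outside the ",
      "proteomic testing pathway (policy error)"))
  }
  if (r$egfr_status == "negative") {
    if (r$egfr_result_date <= r$vs_order_date) {
      return(new_decision(r$patient_id, "testing", "green", "T1",
        "EGFR negative documented before proteomic order"))
    }
    return(new_decision(r$patient_id, "testing", "red", "T2",
      "proteomic test ordered before EGFR result was available"))
  }
  if (r$histology == "squamous") {
    return(new_decision(r$patient_id, "testing", "green", "T3",
      "squamous histology exempts from EGFR testing"))
  }
  if (identical(r$no_egfr_reason, "no_tissue")) {
    return(new_decision(r$patient_id, "testing", "green", "T4",
      "no tissue for EGFR testing; serum proteomic test is the intended fallback"))
  }
  new_decision(r$patient_id, "testing", "yellow", "T5",
    "EGFR not performed in non-squamous disease, reason undocumented")
}

#' Classify the treatment decision for one patient
#'
#' First-match rules, in order:
#' \describe{
#'   \item{X1 (red)}{Erlotinib started before the proteomic timing reference
#'     (result date by default): the result could not have informed the
#'     prescription. Timing dominates result agreement.}
#'   \item{X2 (red)}{Erlotinib given despite a "poor" result, which predicts
#'     greater benefit from chemotherapy.}
#'   \item{X3 (green)}{"Good" result followed by erlotinib.}
#'   \item{X4 (green)}{"Poor" result and no erlotinib.}
#'   \item{X5 (green)}{"Good" result, no erlotinib, patient died within the
#'     end-of-life window of the proteomic order and the departure is
#'     documented as justified (end-of-life exception; see
#'     [decision_policy()]).}
#'   \item{X6 (yellow)}{"Good" result but no erlotinib: the test appears to
#'     have been used for prognosis only.}
#' }
#'
#' @inheritParams classify_testing_decision
#' @return A one-row decisions tibble.
#' @export
classify_treatment_decision <- function(record, policy = decision_policy()) {
  stopifnot(nrow(record) == 1L)
  r <- as.list(record)
  treated <- !is.na(r$erlotinib_start_date)
  ref_date <- if (policy$timing_reference == "result_date") {
    r$vs_result_date
  } else {
    r$vs_order_date
  }
  if (treated && r$erlotinib_start_date < ref_date) {
    return(new_decision(r$patient_id, "treatment", "red", "X1",
      paste0("erlotinib started before the proteomic ",
             sub("_date$", "", policy$timing_reference))))
  }
  if (r$vs_result == "poor" && treated) {
    return(new_decision(r$patient_id, "treatment", "red", "X2",
      "erlotinib given despite 'poor' proteomic status"))
  }
  if (r$vs_result == "good" && treated) {
    return(new_decision(r$patient_id, "treatment", "green", "X3",
      "'good' proteomic status followed by erlotinib"))
  }
  if (r$vs_result == "poor") {
    return(new_decision(r$patient_id, "treatment", "green", "X4",
      "'poor' proteomic status and no erlotinib"))
  }
  if (policy$eol_exception_enabled &&
      tested_near_death(record, policy$eol_window_days) &&
      isTRUE(r$treatment_justification_documented)) {
    return(new_decision(r$patient_id, "treatment", "green", "X5",
      "no erlotinib despite 'good' status; end-of-life departure documented"))
  }
  new_decision(r$patient_id, "treatment", "yellow", "X6",
    "'good' proteomic status but no erlotinib; prognostic-only use")
}

#' Extract and classify both decisions for every patient
#'
#' Runs [classify_testing_decision()] and [classify_treatment_decision()] on
#' each record, yielding exactly two decisions per patient (testing first).
#' Records are validated first; any error-severity violation aborts with the
#' offending patient IDs.
#'
#' @param cohort A cohort tibble.
#' @param policy A [decision_policy()].
#' @return A decisions tibble with `2 * nrow(cohort)` rows.
#' @export
#' @examples
#' extract_decisions(build_fixture_cohort())  # 138 decisions
extract_decisions <- function(cohort, policy = decision_policy()) {
  if (nrow(cohort) == 0L) {
    return(new_decision(character(), character(), character(),
                        character(), character()))
  }
  issues <- validate_cohort(cohort)
  bad <- unique(issues$patient_id[issues$severity == "error"])
  if (length(bad) > 0L) {
    rlang::abort(paste0("cohort contains invalid record(s): ",
                        paste(bad, collapse = ", ")))
  }
  df <- as.data.frame(cohort)  # row extraction is far cheaper than on tibbles
  n <- nrow(df)
  out <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    rec <- df[i, , drop = FALSE]
    tryCatch({
      out[[2L * i - 1L]] <- classify_testing_decision(rec, policy)
      out[[2L * i]] <- classify_treatment_decision(rec, policy)
    }, error = function(e) {
      rlang::abort(paste0("patient ", rec$patient_id, ": ",
                          conditionMessage(e)))
    })
  }
  tibble::new_tibble(
    lapply(stats::setNames(nm = names(out[[1L]])),
           function(col) vapply(out, function(d) d[[col]], character(1))),
    nrow = 2L * n)
}

#' Timing-agnostic result concordance
#'
#' `TRUE` when erlotinib use agrees with the proteomic result irrespective of
#' any dates: a "good" patient who received the drug (even before the result
#' returned) or a "poor" patient who did not. This is the summary-tree view
#' of utilization, deliberately blind to decision timing.
#'
#' @param record A cohort tibble (vectorized over rows).
#' @return A logical vector, one value per record.
#' @export
result_only_concordant <- function(record) {
  treated <- !is.na(record$erlotinib_start_date)
  (record$vs_result == "good" & treated) |
    (record$vs_result == "poor" & !treated)
}

#' Enumerate the full rule table
#'
#' Builds one synthetic record for every realizable combination of histology
#' class, EGFR pathway position, proteomic result, erlotinib timing and
#' end-of-life/justification status, and records the engine's classification
#' of each. Supports exhaustive comparison against an independently written
#' lookup oracle.
#'
#' Realizability: the "EGFR skipped for squamous histology" branch requires
#' squamous histology, and the no-tissue / undocumented branches are
#' non-squamous (a squamous tumor is already exempt).
#'
#' @param policy A [decision_policy()].
#' @return A tibble with one row per combination: the five attribute columns
#'   plus `testing_code`, `testing_rule`, `treatment_code`, `treatment_rule`.
#' @export
enumerate_rule_table <- function(policy = decision_policy()) {
  grid <- expand.grid(
    histology_class = c("squamous", "non_squamous"),
    egfr = c("negative_before", "negative_after", "np_squamous",
             "np_no_tissue", "np_undocumented"),
    vs = c("good", "poor"),
    erlotinib = c("none", "before_result", "after_result"),
    eol_justified = c(FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  realizable <-
    (grid$egfr == "np_squamous") == (grid$histology_class == "squamous") |
    grid$egfr %in% c("negative_before", "negative_after")
  realizable <- realizable &
    !(grid$histology_class == "squamous" &
        grid$egfr %in% c("np_no_tissue", "np_undocumented"))
  grid <- grid[realizable, , drop = FALSE]
  rownames(grid) <- NULL

  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    rec <- rule_table_record(g)
    td <- classify_testing_decision(rec, policy)
    xd <- classify_treatment_decision(rec, policy)
    tibble::tibble(
      histology_class = g$histology_class, egfr = g$egfr, vs = g$vs,
      erlotinib = g$erlotinib, eol_justified = g$eol_justified,
      testing_code = td$code, testing_rule = td$rule_id,
      treatment_code = xd$code, treatment_rule = xd$rule_id
    )
  })
  dplyr::bind_rows(rows)
}

# Canonical dates: diagnosis day 0, proteomic order day 60, result day 74.
rule_table_record <- function(g) {
  base <- as.Date("2013-01-01")
  egfr_status <- if (startsWith(g$egfr, "negative")) "negative" else "not_performed"
  patient_record(
    patient_id = "ENUM",
    histology = if (g$histology_class == "squamous") "squamous" else "adenocarcinoma",
    diagnosis_date = base,
    egfr_status = egfr_status,
    egfr_result_date = switch(g$egfr,
      negative_before = base + 30, negative_after = base + 120, NA),
    no_egfr_reason = switch(g$egfr,
      np_squamous = "squamous", np_no_tissue = "no_tissue",
      np_undocumented = "undocumented", "not_applicable"),
    tissue_sufficient = if (g$egfr == "np_no_tissue") "no" else "yes",
    vs_order_date = base + 60,
    vs_result_date = base + 74,
    vs_result = g$vs,
    erlotinib_start_date = switch(g$erlotinib,
      none = NA, before_result = base + 65, after_result = base + 84),
    erlotinib_days_supplied = if (g$erlotinib == "none") NA else 30L,
    death_date = if (g$eol_justified) base + 120 else NA,
    treatment_justification_documented = g$eol_justified
  )
}
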