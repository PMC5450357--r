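# Cost-of-care model: per-patient pathway costs and the spend attributable
# to clearly non-concordant (red) decisions.

#' Unit-cost schedule
#'
#' Default unit costs in US dollars: \$500 for an EGFR mutation test, \$2,112
#' for the serum proteomic test, and \$4,815 for a 30-day supply of erlotinib
#' (100 mg). Erlotinib is billed in 30-day blocks, rounded up, so a 63-day
#' course costs three months' supply.
#'
#' @param egfr_test_cost,proteomic_test_cost,erlotinib_monthly_cost
#'   Non-negative dollar amounts.
#' @return A list of class `cost_schedule`.
#' @export
cost_schedule <- function(egfr_test_cost = 500,
                          proteomic_test_cost = 2112,
                          erlotinib_monthly_cost = 4815) {
  costs <- c(egfr_test_cost, proteomic_test_cost, erlotinib_monthly_cost)
  if (any(is.na(costs)) || any(costs < 0)) {
    rlang::abort("all unit costs must be non-negative")
  }
  structure(
    list(egfr_test_cost = as.numeric(egfr_test_cost),
         proteomic_test_cost = as.numeric(proteomic_test_cost),
         erlotinib_monthly_cost = as.numeric(erlotinib_monthly_cost)),
    class = "cost_schedule"
  )
}

erlotinib_supply_cost <- function(days_supplied, schedule) {
  blocks <- ifelse(is.na(days_supplied), 0, ceiling(days_supplied / 30))
  blocks * schedule$erlotinib_monthly_cost
}

#' Per-patient pathway cost
#'
#' Sums the events on the patient's pathway: the EGFR test when performed,
#' the proteomic test (always, in this cohort), and erlotinib supply in
#' 30-day blocks rounded up.
#'
#' @param record A cohort tibble (vectorized over rows).
#' @param schedule A [cost_schedule()].
#' @return A numeric vector of dollar amounts, one per record.
#' @export
#' @examples
#' pathway_cost(patient_record(egfr_status = "not_performed",
#'                             egfr_result_date = NA,
#'                             no_egfr_reason = "undocumented"))  # 2112
pathway_cost <- function(record, schedule = cost_schedule()) {
  egfr_done <- record$egfr_status %in% c("negative", "positive")
  egfr_done * schedule$egfr_test_cost +
    schedule$proteomic_test_cost +
    erlotinib_supply_cost(record$erlotinib_days_supplied, schedule)
}

#' Spend attributable to non-concordant decisions
#'
#' Attributes cost to clear departures: when a patient's testing decision is
#' red, the proteomic test cost is counted (the test was ordered out of
#' sequence); when the treatment decision is red, the erlotinib supply cost
#' is counted (the prescription was not informed by, or contradicted, the
#' result). Concordant and questionable (green/yellow) decisions attribute
#' nothing.
#'
#' @param record A one-row cohort tibble.
#' @param decisions That patient's decision pair, e.g. the matching rows of
#'   [extract_decisions()] output.
#' @param schedule A [cost_schedule()].
#' @return A dollar amount.
#' @export
nonconcordant_spend <- function(record, decisions,
                                schedule = cost_schedule()) {
  stopifnot(nrow(record) == 1L)
  if (!all(decisions$patient_id == record$patient_id)) {
    rlang::abort("decisions do not belong to this patient")
  }
  testing_red <- any(decisions$decision_kind == "testing" &
                       decisions$code == "red")
  treatment_red <- any(decisions$decision_kind == "treatment" &
                         decisions$code == "red")
  testing_red * schedule$proteomic_test_cost +
    treatment_red * erlotinib_supply_cost(record$erlotinib_days_supplied,
                                          schedule)
}
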