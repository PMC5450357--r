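# Audit-report assembly and JSON serialization.

#' Assemble the audit report
#'
#' Aggregates the classified decisions, the utilization/demographic summary
#' and the cost model into a single JSON-serializable report: decision
#' totals by color (with integer half-up percentages over all decisions),
#' totals by decision kind, per-rule firing counts, total pathway cost and
#' the spend attributable to red decisions, the policy in force, and
#' provenance.
#'
#' @param cohort A valid cohort tibble.
#' @param decisions The decisions extracted from `cohort` under `policy`
#'   (exactly two per patient; anything else is a contract violation).
#' @param schedule A [cost_schedule()].
#' @param policy The [decision_policy()] the decisions were produced under.
#' @param provenance Optional named list recorded verbatim (input path,
#'   seed, ...).
#' @return A list of class `audit_report`.
#' @export
#' @examples
#' cohort <- build_fixture_cohort()
#' report <- build_report(cohort, extract_decisions(cohort))
#' report$decision_totals$counts
build_report <- function(cohort, decisions,
                         schedule = cost_schedule(),
                         policy = decision_policy(),
                         provenance = list()) {
  n <- nrow(cohort)
  if (n == 0L || nrow(decisions) != 2L * n) {
    rlang::abort(paste0(
      "decisions must contain exactly 2 decisions per patient (got ",
      nrow(decisions), " for ", n, " patients)"))
  }
  per_patient <- table(decisions$patient_id, decisions$decision_kind)
  if (!setequal(rownames(per_patient), cohort$patient_id) ||
      any(per_patient != 1L)) {
    rlang::abort(
      "each patient requires exactly one testing and one treatment decision")
  }

  n_dec <- nrow(decisions)
  color_counts <- stats::setNames(
    as.integer(table(factor(decisions$code, levels = DECISION_CODES))),
    DECISION_CODES)
  color_pct <- stats::setNames(
    vapply(color_counts, pct_int, integer(1), denom = n_dec),
    DECISION_CODES)
  by_kind <- lapply(stats::setNames(DECISION_KINDS, DECISION_KINDS),
    function(k) {
      sub <- decisions$code[decisions$decision_kind == k]
      stats::setNames(
        as.integer(table(factor(sub, levels = DECISION_CODES))),
        DECISION_CODES)
    })
  rule_counts <- table(decisions$rule_id)
  rule_counts <- stats::setNames(as.integer(rule_counts), names(rule_counts))
  rule_counts <- rule_counts[order(names(rule_counts))]

  nc_spend <- vapply(seq_len(n), function(i) {
    rec <- cohort[i, ]
    nonconcordant_spend(
      rec, decisions[decisions$patient_id == rec$patient_id, ], schedule)
  }, numeric(1))

  structure(list(
    summary = unclass(summarize_cohort(cohort, policy)),
    decision_totals = list(counts = color_counts, percentages = color_pct),
    decision_totals_by_kind = by_kind,
    rule_firing_counts = rule_counts,
    cost_total = sum(pathway_cost(cohort, schedule)),
    nonconcordant_cost_total = sum(nc_spend),
    policy_echo = unclass(policy),
    cost_schedule_echo = unclass(schedule),
    provenance = c(list(n_records = n, n_decisions = n_dec), provenance)
  ), class = "audit_report")
}

#' Read and write audit reports as JSON
#'
#' Reports serialize to a stable JSON layout: named objects for every
#' mapping, scalars unboxed, numbers at full precision. Serializing a
#' report, parsing it and serializing again is byte-identical.
#'
#' @param report An `audit_report` (or a list previously read by
#'   [read_report()]).
#' @param path Output (input) file path.
#' @return `write_report()`: `path`, invisibly. `read_report()`: the report
#'   as a nested list.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass_deep(report), path,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path)
}

# jsonlite serializes named vectors as arrays; nested named lists give the
# stable object layout the report promises.
unclass_deep <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  if (!is.null(names(x)) && length(x) > 0L) return(as.list(x))
  x
}

#' @export
print.audit_report <- function(x, ...) {
  ct <- x$decision_totals$counts
  pc <- x$decision_totals$percentages
  cat("Audit report:", x$summary$n_patients, "patients,",
      x$provenance$n_decisions, "clinical decisions\n")
  cat(sprintf("  green  %3d (%d%%)  concordant with the testing algorithm\n",
              ct[["green"]], pc[["green"]]))
  cat(sprintf("  yellow %3d (%d%%)  questionable or under-documented\n",
              ct[["yellow"]], pc[["yellow"]]))
  cat(sprintf("  red    %3d (%d%%)  clear departures\n",
              ct[["red"]], pc[["red"]]))
  cat(sprintf("  pathway cost total: $%s; attributable to red decisions: $%s\n",
              format(x$cost_total, big.mark = ","),
              format(x$nonconcordant_cost_total, big.mark = ",")))
  invisible(x)
}
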