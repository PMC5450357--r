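# Timing intervals, end-of-life flags, and cohort utilization summaries.

#' Signed whole-day interval between two dates
#'
#' @param a,b Calendar dates (`Date` or ISO 8601 string); both must be
#'   present.
#' @return Integer `b - a` in days (negative when `b` precedes `a`).
#' @export
#' @examples
#' days_between("2014-01-01", "2014-02-12")  # 42
days_between <- function(a, b) {
  a <- as_record_date(a)
  b <- as_record_date(b)
  if (anyNA(a) || anyNA(b)) {
    rlang::abort("days_between requires both dates to be present")
  }
  as.integer(b - a)
}

#' Was the proteomic test ordered near the end of life?
#'
#' `TRUE` when the patient died and the proteomic order fell within
#' `window_days` days before death (both endpoints inclusive: a test on the
#' death day counts, a test `window_days` before death counts). Measured
#' from the order date, the day the clinical decision to test was made.
#'
#' @param record A cohort tibble (vectorized over rows).
#' @param window_days End-of-life window in days (default 90).
#' @return A logical vector, one value per record.
#' @export
tested_near_death <- function(record, window_days = 90L) {
  gap <- as.integer(record$death_date - record$vs_order_date)
  !is.na(gap) & gap >= 0L & gap <= as.integer(window_days)
}

# round() uses banker's rounding; printed percentages use half-up.
round_half_up <- function(x, digits = 0) {
  floor(x * 10^digits + 0.5) / 10^digits
}

pct_int <- function(num, denom) {
  as.integer(round_half_up(100 * num / denom))
}

#' Summarize test utilization and demographics for a cohort
#'
#' Computes the utilization tree (EGFR status, proteomic results, erlotinib
#' exposure by result, timing-agnostic result concordance), end-of-life
#' testing counts, and the demographic profile (age mean/SD and decade bands,
#' race, site of care, histology). Percentages are integer, rounded half-up;
#' age mean and sample SD are reported to one decimal.
#'
#' @param cohort A non-empty, valid cohort tibble.
#' @param policy A [decision_policy()]; supplies the end-of-life window.
#' @return A list of class `utilization_summary`.
#' @export
#' @examples
#' s <- summarize_cohort(build_fixture_cohort())
#' s$near_death_tested_count  # 9
summarize_cohort <- function(cohort, policy = decision_policy()) {
  if (nrow(cohort) == 0L) {
    rlang::abort("summarize_cohort requires a non-empty cohort")
  }
  n <- nrow(cohort)
  treated <- !is.na(cohort$erlotinib_start_date)
  good <- cohort$vs_result == "good"
  near_death <- tested_near_death(cohort, policy$eol_window_days)
  # "treated near death": erlotinib also started within the window of death
  erl_gap <- as.integer(cohort$death_date - cohort$erlotinib_start_date)
  near_death_treated <- near_death & treated &
    !is.na(erl_gap) & erl_gap >= 0L & erl_gap <= policy$eol_window_days

  count_by <- function(x, levels) {
    tab <- table(factor(x, levels = levels))
    stats::setNames(as.integer(tab), levels)
  }
  visn_counts <- sort(table(cohort$visn), decreasing = TRUE)
  top4 <- sum(utils::head(visn_counts, 4L))

  age_bands <- cut(cohort$age, breaks = c(50, 60, 70, 80, 120),
                   right = FALSE, labels = c("50-59", "60-69", "70-79", "80+"))

  structure(list(
    n_patients = n,
    egfr_counts = count_by(cohort$egfr_status, EGFR_LEVELS),
    vs_counts = count_by(cohort$vs_result, VS_LEVELS),
    good_treated = sum(good & treated),
    good_untreated = sum(good & !treated),
    poor_treated = sum(!good & treated),
    poor_untreated = sum(!good & !treated),
    result_concordant_count = sum(result_only_concordant(cohort)),
    result_concordant_pct = pct_int(sum(result_only_concordant(cohort)), n),
    near_death_tested_count = sum(near_death),
    near_death_treated_count = sum(near_death_treated),
    near_death_treated_poor_count = sum(near_death_treated & !good),
    deceased_count = sum(!is.na(cohort$death_date)),
    age_mean = round_half_up(mean(cohort$age), 1),
    age_sd = round_half_up(stats::sd(cohort$age), 1),
    age_band_counts = stats::setNames(as.integer(table(age_bands)),
                                      levels(age_bands)),
    race_counts = count_by(cohort$race, RACE_LEVELS),
    visn_counts = stats::setNames(as.integer(visn_counts), names(visn_counts)),
    top4_visn_share_pct = pct_int(top4, n),
    histology_counts = count_by(cohort$histology, HISTOLOGY_LEVELS)
  ), class = "utilization_summary")
}

#' @export
print.utilization_summary <- function(x, ...) {
  cat("Utilization summary:", x$n_patients, "patients\n")
  cat(sprintf("  EGFR: negative %d, positive %d, not performed %d\n",
              x$egfr_counts[["negative"]], x$egfr_counts[["positive"]],
              x$egfr_counts[["not_performed"]]))
  cat(sprintf("  Proteomic: good %d, poor %d\n",
              x$vs_counts[["good"]], x$vs_counts[["poor"]]))
  cat(sprintf("  Erlotinib by result: good %d/%d treated, poor %d/%d treated\n",
              x$good_treated, x$vs_counts[["good"]],
              x$poor_treated, x$vs_counts[["poor"]]))
  cat(sprintf("  Result-concordant (timing-agnostic): %d/%d (%d%%)\n",
              x$result_concordant_count, x$n_patients,
              x$result_concordant_pct))
  cat(sprintf("  Tested near death: %d (%d treated, %d of those poor)\n",
              x$near_death_tested_count, x$near_death_treated_count,
              x$near_death_treated_poor_count))
  cat(sprintf("  Age: mean %.1f (SD %.1f); top-4 site share %d%%\n",
              x$age_mean, x$age_sd, x$top4_visn_share_pct))
  invisible(x)
}
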