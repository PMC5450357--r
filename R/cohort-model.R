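# Patient-level cohort data model: schema, constructors, validation, I/O.
#
# A cohort is a tibble with one row per patient. Every patient in scope has
# exactly one proteomic (VeriStrat) test; EGFR testing and erlotinib exposure
# are optional. Dates are calendar dates (day resolution); intra-day ordering
# is not modelled.

#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Enum levels, serialized lowercase in CSV/JSON.
RACE_LEVELS <- c("white", "black", "other")
HISTOLOGY_LEVELS <- c("adenocarcinoma", "squamous", "mixed",
                      "large_cell_neuroendocrine", "unspecified")
TISSUE_LEVELS <- c("yes", "no", "unknown")
EGFR_LEVELS <- c("negative", "positive", "not_performed")
VS_LEVELS <- c("good", "poor")
NO_EGFR_REASON_LEVELS <- c("not_applicable", "squamous", "no_tissue",
                           "undocumented")
DECISION_CODES <- c("green", "yellow", "red")
DECISION_KINDS <- c("testing", "treatment")

# Fixed column order of the cohort CSV schema.
COHORT_COLUMNS <- c(
  "patient_id", "age", "race", "visn", "histology", "diagnosis_date",
  "death_date", "biopsy_performed", "tissue_sufficient", "egfr_status",
  "egfr_result_date", "vs_order_date", "vs_result_date", "vs_result",
  "erlotinib_start_date", "erlotinib_days_supplied", "no_egfr_reason",
  "treatment_justification_documented"
)

DATE_COLUMNS <- c("diagnosis_date", "death_date", "egfr_result_date",
                  "vs_order_date", "vs_result_date", "erlotinib_start_date")
LOGICAL_COLUMNS <- c("biopsy_performed", "treatment_justification_documented")
INTEGER_COLUMNS <- c("age", "erlotinib_days_supplied")

#' Construct a single patient record
#'
#' Builds a one-row cohort tibble with sensible defaults for a well-formed
#' record (EGFR-negative before the proteomic order, proteomic "good", no
#' erlotinib). Intended for tests, rule-table enumeration and small examples;
#' cohorts of real or simulated patients come from [read_cohort()],
#' [build_fixture_cohort()] or [simulate_cohort()].
#'
#' @param patient_id Opaque string identifier.
#' @param age Integer age in years (50 or older).
#' @param race One of `"white"`, `"black"`, `"other"`.
#' @param visn Site-of-care label, e.g. `"VISN 17"`.
#' @param histology One of `"adenocarcinoma"`, `"squamous"`, `"mixed"`,
#'   `"large_cell_neuroendocrine"`, `"unspecified"`.
#' @param diagnosis_date,death_date,egfr_result_date,vs_order_date,vs_result_date,erlotinib_start_date
#'   Calendar dates (`Date` or ISO 8601 string); `NA` where the event did not
#'   occur.
#' @param biopsy_performed Logical.
#' @param tissue_sufficient One of `"yes"`, `"no"`, `"unknown"`.
#' @param egfr_status One of `"negative"`, `"positive"`, `"not_performed"`.
#' @param vs_result Proteomic result, `"good"` or `"poor"`.
#' @param erlotinib_days_supplied Total days of erlotinib supplied, `NA` when
#'   the drug was never dispensed.
#' @param no_egfr_reason Reason EGFR testing was not performed:
#'   `"not_applicable"` (it was performed), `"squamous"`, `"no_tissue"` or
#'   `"undocumented"`.
#' @param treatment_justification_documented Logical; whether the chart
#'   documents a valid clinical reason for a departure from the treatment
#'   algorithm.
#'
#' @return A one-row tibble in the cohort schema.
#' @export
#' @examples
#' rec <- patient_record(vs_result = "poor")
#' validate_record(rec)
patient_record <- function(patient_id = "P1",
                           age = 68L,
                           race = "white",
                           visn = "VISN 17",
                           histology = "adenocarcinoma",
                           diagnosis_date = "2013-01-01",
                           death_date = NA,
                           biopsy_performed = TRUE,
                           tissue_sufficient = "yes",
                           egfr_status = "negative",
                           egfr_result_date = "2013-02-01",
                           vs_order_date = "2013-03-01",
                           vs_result_date = "2013-03-15",
                           vs_result = "good",
                           erlotinib_start_date = NA,
                           erlotinib_days_supplied = NA,
                           no_egfr_reason = "not_applicable",
                           treatment_justification_documented = FALSE) {
  tibble(
    patient_id = as.character(patient_id),
    age = as.integer(age),
    race = as.character(race),
    visn = as.character(visn),
    histology = as.character(histology),
    diagnosis_date = as_record_date(diagnosis_date),
    death_date = as_record_date(death_date),
    biopsy_performed = as.logical(biopsy_performed),
    tissue_sufficient = as.character(tissue_sufficient),
    egfr_status = as.character(egfr_status),
    egfr_result_date = as_record_date(egfr_result_date),
    vs_order_date = as_record_date(vs_order_date),
    vs_result_date = as_record_date(vs_result_date),
    vs_result = as.character(vs_result),
    erlotinib_start_date = as_record_date(erlotinib_start_date),
    erlotinib_days_supplied = as.integer(erlotinib_days_supplied),
    no_egfr_reason = as.character(no_egfr_reason),
    treatment_justification_documented =
      as.logical(treatment_justification_documented)
  )
}

as_record_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  if (all(is.na(x))) return(as.Date(rep(NA_character_, length(x))))
  as.Date(as.character(x), format = "%Y-%m-%d")
}

#' Validate patient records against the cohort invariants
#'
#' Checks every structural invariant of the data model: event ordering
#' (proteomic result on or after its order; death on or after diagnosis),
#' consistency of EGFR status, result date and no-test reason, paired
#' erlotinib start/supply fields with positive days supplied, age bounds and
#' enum membership. Violations are returned, never raised.
#'
#' @param cohort A cohort tibble (any number of rows).
#' @param record A one-row cohort tibble.
#'
#' @return A tibble of validation issues with columns `patient_id`, `field`,
#'   `message`, `severity` (`"error"` or `"warning"`). Zero rows means every
#'   record is usable. Records carrying an `error` issue must be excluded from
#'   downstream stages; [read_cohort()] does this automatically.
#' @export
#' @examples
#' validate_record(patient_record())                      # clean: 0 issues
#' bad <- patient_record(egfr_result_date = NA)           # negative w/o date
#' validate_record(bad)
validate_cohort <- function(cohort) {
  issues <- list()
  add <- function(mask, field, message, severity = "error") {
    mask[is.na(mask)] <- FALSE
    if (any(mask)) {
      issues[[length(issues) + 1L]] <<- tibble(
        patient_id = cohort$patient_id[mask],
        field = field, message = message, severity = severity
      )
    }
  }

  add(is.na(cohort$patient_id) | cohort$patient_id == "",
      "patient_id", "patient_id is required")
  add(is.na(cohort$diagnosis_date), "diagnosis_date",
      "diagnosis_date is required")
  add(is.na(cohort$vs_order_date), "vs_order_date",
      "proteomic order date is required")
  add(is.na(cohort$vs_result_date), "vs_result_date",
      "proteomic result date is required")

  add(!is.na(cohort$vs_order_date) & !is.na(cohort$vs_result_date) &
        cohort$vs_result_date < cohort$vs_order_date,
      "vs_result_date",
      "proteomic result date precedes its order date")

  add(!cohort$egfr_status %in% EGFR_LEVELS, "egfr_status",
      paste("egfr_status must be one of:", paste(EGFR_LEVELS, collapse = ", ")))
  add(cohort$egfr_status == "not_performed" & !is.na(cohort$egfr_result_date),
      "egfr_result_date",
      "EGFR not performed but a result date is present")
  add(cohort$egfr_status %in% c("negative", "positive") &
        is.na(cohort$egfr_result_date),
      "egfr_result_date",
      "EGFR performed but no result date recorded")
  add(cohort$egfr_status == "not_performed" &
        cohort$no_egfr_reason == "not_applicable",
      "no_egfr_reason",
      "EGFR not performed requires a no-test reason")
  add(cohort$egfr_status %in% c("negative", "positive") &
        cohort$no_egfr_reason != "not_applicable",
      "no_egfr_reason",
      "EGFR performed but a no-test reason is recorded")

  add(!is.na(cohort$erlotinib_start_date) &
        is.na(cohort$erlotinib_days_supplied),
      "erlotinib_days_supplied",
      "erlotinib start date without days supplied")
  add(is.na(cohort$erlotinib_start_date) &
        !is.na(cohort$erlotinib_days_supplied),
      "erlotinib_start_date",
      "erlotinib days supplied without a start date")
  add(!is.na(cohort$erlotinib_days_supplied) &
        cohort$erlotinib_days_supplied <= 0L,
      "erlotinib_days_supplied", "days supplied must be positive")

  add(!is.na(cohort$death_date) & !is.na(cohort$diagnosis_date) &
        cohort$death_date < cohort$diagnosis_date,
      "death_date", "death date precedes diagnosis date")

  add(is.na(cohort$age) | cohort$age < 50L | cohort$age >= 120L,
      "age", "age must be an integer in [50, 120)")

  add(!cohort$vs_result %in% VS_LEVELS, "vs_result",
      "vs_result must be 'good' or 'poor'")
  add(!cohort$histology %in% HISTOLOGY_LEVELS, "histology",
      paste("histology must be one of:",
            paste(HISTOLOGY_LEVELS, collapse = ", ")))
  add(!cohort$no_egfr_reason %in% NO_EGFR_REASON_LEVELS, "no_egfr_reason",
      paste("no_egfr_reason must be one of:",
            paste(NO_EGFR_REASON_LEVELS, collapse = ", ")))

  # Descriptive fields: flagged but usable.
  add(!is.na(cohort$race) & !cohort$race %in% RACE_LEVELS,
      "race", "unrecognized race label", severity = "warning")
  add(!is.na(cohort$tissue_sufficient) &
        !cohort$tissue_sufficient %in% TISSUE_LEVELS,
      "tissue_sufficient", "unrecognized tissue label", severity = "warning")

  if (length(issues) == 0L) return(empty_issues())
  dplyr::arrange(dplyr::bind_rows(issues), .data$patient_id, .data$field)
}

#' @rdname validate_cohort
#' @export
validate_record <- function(record) {
  stopifnot(nrow(record) == 1L)
  validate_cohort(record)
}

empty_issues <- function() {
  tibble(patient_id = character(), field = character(),
         message = character(), severity = character())
}

#' Read a patient cohort from CSV or JSON
#'
#' Parses a cohort table in the published column schema, coerces types
#' (ISO 8601 dates, lowercase `true`/`false` logicals, empty string for
#' absent), and validates every row. Rows with a malformed date or any
#' error-severity invariant violation are excluded; all issues are attached
#' to the result as the `"issues"` attribute. Unknown columns are dropped
#' with a warning; row order is preserved.
#'
#' @param source Path to a CSV or JSON file (JSON: an array of objects).
#' @param format `"csv"` or `"json"`.
#'
#' @return A cohort tibble of the usable records, with attribute `issues`
#'   (see [validate_cohort()]).
#' @export
read_cohort <- function(source, format = c("csv", "json")) {
  format <- match.arg(format)
  raw <- switch(format,
    csv = readr::read_csv(source, col_types = readr::cols(.default = "c"),
                          na = character(), progress = FALSE),
    json = {
      parsed <- jsonlite::fromJSON(source, simplifyVector = TRUE)
      if (length(parsed) == 0L) {
        as_tibble(stats::setNames(
          rep(list(character()), length(COHORT_COLUMNS)), COHORT_COLUMNS))
      } else {
        dplyr::mutate(as_tibble(parsed),
                      dplyr::across(dplyr::everything(), as.character))
      }
    }
  )

  missing_cols <- setdiff(COHORT_COLUMNS, names(raw))
  if (length(missing_cols) > 0L) {
    abort(paste0("cohort source is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  extra <- setdiff(names(raw), COHORT_COLUMNS)
  if (length(extra) > 0L) {
    warn(paste0("ignoring unknown column(s): ", paste(extra, collapse = ", ")))
  }
  raw <- raw[COHORT_COLUMNS]
  raw[] <- lapply(raw, function(x) ifelse(!is.na(x) & x == "", NA, x))

  # Malformed dates become row-level errors, not parser warnings.
  date_issues <- list()
  for (col in DATE_COLUMNS) {
    txt <- raw[[col]]
    bad <- !is.na(txt) & !grepl("^\\d{4}-\\d{2}-\\d{2}$", txt)
    parsed <- as.Date(ifelse(bad, NA, txt), format = "%Y-%m-%d")
    bad <- bad | (!is.na(txt) & is.na(parsed))
    if (any(bad)) {
      date_issues[[col]] <- tibble(
        patient_id = as.character(raw$patient_id[bad]), field = col,
        message = paste0("unparseable date '", txt[bad], "' (expected ISO 8601)"),
        severity = "error")
    }
    raw[[col]] <- parsed
  }
  for (col in LOGICAL_COLUMNS) raw[[col]] <- parse_logical_field(raw[[col]])
  for (col in INTEGER_COLUMNS) raw[[col]] <- suppressWarnings(as.integer(raw[[col]]))

  cohort <- as_tibble(raw)
  issues <- dplyr::bind_rows(c(date_issues, list(validate_cohort(cohort))))
  if (nrow(issues) == 0L) issues <- empty_issues()

  bad_ids <- unique(issues$patient_id[issues$severity == "error"])
  if (length(bad_ids) > 0L) {
    warn(paste0("excluding ", length(bad_ids),
                " record(s) with validation errors: ",
                paste(bad_ids, collapse = ", ")))
    cohort <- cohort[!cohort$patient_id %in% bad_ids, ]
  }
  attr(cohort, "issues") <- issues
  cohort
}

parse_logical_field <- function(x) {
  out <- rep(NA, length(x))
  out[tolower(x) %in% c("true", "t", "1")] <- TRUE
  out[tolower(x) %in% c("false", "f", "0")] <- FALSE
  out
}

#' Write a cohort to CSV in the published schema
#'
#' Columns appear in the fixed schema order; absent values are written as the
#' empty string, dates as ISO 8601, logicals as lowercase `true`/`false`.
#' [read_cohort()] of the output reproduces the records field-for-field.
#'
#' @param cohort A cohort tibble.
#' @param sink Output file path.
#' @return `sink`, invisibly.
#' @export
write_cohort <- function(cohort, sink) {
  out <- cohort[COHORT_COLUMNS]
  for (col in DATE_COLUMNS) out[[col]] <- format(out[[col]], "%Y-%m-%d")
  for (col in LOGICAL_COLUMNS) {
    out[[col]] <- ifelse(is.na(out[[col]]), NA_character_,
                         ifelse(out[[col]], "true", "false"))
  }
  readr::write_csv(out, sink, na = "", progress = FALSE)
  invisible(sink)
}

#' Write classified decisions to CSV
#'
#' One row per decision with header
#' `patient_id,decision_kind,code,rule_id,rationale`, ordered by patient then
#' testing before treatment so output is stable across runs.
#'
#' @param decisions A decisions tibble, e.g. from [extract_decisions()].
#' @param sink Output file path.
#' @return `sink`, invisibly.
#' @export
write_decisions <- function(decisions, sink) {
  cols <- c("patient_id", "decision_kind", "code", "rule_id", "rationale")
  if (nrow(decisions) == 0L) {
    out <- as_tibble(stats::setNames(rep(list(character()), length(cols)), cols))
  } else {
    out <- decisions[cols]
    out <- out[order(out$patient_id,
                     match(out$decision_kind, DECISION_KINDS)), ]
  }
  readr::write_csv(out, sink, na = "", progress = FALSE)
  invisible(sink)
}
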