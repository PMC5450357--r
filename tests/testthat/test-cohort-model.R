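# Cohort data model: validation, CSV/JSON I/O, round-trips.

test_that("well-formed records validate cleanly and violations are reported", {
  expect_identical(nrow(validate_record(patient_record())), 0L)

  # each forced invariant produces exactly one error issue
  cases <- list(
    list(rec = patient_record(egfr_result_date = NA),
         field = "egfr_result_date"),
    list(rec = patient_record(erlotinib_start_date = "2013-04-01"),
         field = "erlotinib_days_supplied"),
    list(rec = patient_record(vs_order_date = "2013-03-20",
                              vs_result_date = "2013-03-10"),
         field = "vs_result_date"),
    list(rec = patient_record(death_date = "2012-06-01"),
         field = "death_date"),
    list(rec = patient_record(age = 49L), field = "age"),
    list(rec = patient_record(erlotinib_start_date = "2013-04-01",
                              erlotinib_days_supplied = 0L),
         field = "erlotinib_days_supplied")
  )
  for (case in cases) {
    issues <- validate_record(case$rec)
    expect_identical(issues$field, case$field)
    expect_identical(issues$severity, "error")
  }
})

test_that("validation is pure and consistent across single and cohort form", {
  rec <- patient_record(egfr_status = "not_performed", egfr_result_date = NA,
                        no_egfr_reason = "not_applicable")
  expect_identical(validate_record(rec), validate_record(rec))
  cohort <- dplyr::bind_rows(patient_record(patient_id = "A"),
                             rec |> dplyr::mutate(patient_id = "B"))
  issues <- validate_cohort(cohort)
  expect_identical(unique(issues$patient_id), "B")
})

test_that("cohort CSV round-trips field-identically", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(fixture_cohort, path)
  back <- read_cohort(path)
  expect_identical(nrow(attr(back, "issues")), 0L)
  attr(back, "issues") <- NULL
  expect_equal(as.data.frame(back), as.data.frame(fixture_cohort))
})

test_that("JSON cohorts parse to the same records as CSV", {
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_cohort(fixture_cohort, csv)
  out <- fixture_cohort
  for (col in c("diagnosis_date", "death_date", "egfr_result_date",
                "vs_order_date", "vs_result_date", "erlotinib_start_date")) {
    out[[col]] <- format(out[[col]], "%Y-%m-%d")
  }
  jsonlite::write_json(out, js, na = "null")
  from_csv <- read_cohort(csv, format = "csv")
  from_json <- read_cohort(js, format = "json")
  expect_equal(as.data.frame(from_json), as.data.frame(from_csv))
})

test_that("header-only file yields an empty cohort", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(fixture_cohort[0, ], path)
  back <- read_cohort(path)
  expect_identical(nrow(back), 0L)
})

test_that("missing required columns and unknown columns are handled", {
  path <- withr::local_tempfile(fileext = ".csv")
  broken <- fixture_cohort
  broken$vs_result <- NULL
  readr::write_csv(broken, path, na = "")
  expect_error(read_cohort(path), "vs_result")

  write_cohort(fixture_cohort, path)
  txt <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  txt$mystery_extra <- "x"
  readr::write_csv(txt, path, na = "")
  expect_warning(back <- read_cohort(path), "mystery_extra")
  expect_identical(nrow(back), 69L)
})

test_that("rows violating invariants or with bad dates are excluded with issues", {
  path <- withr::local_tempfile(fileext = ".csv")
  bad <- patient_record(patient_id = "BAD", vs_order_date = "2013-03-20",
                        vs_result_date = "2013-03-10")
  write_cohort(dplyr::bind_rows(patient_record(patient_id = "OK"), bad), path)
  expect_warning(back <- read_cohort(path), "BAD")
  expect_identical(back$patient_id, "OK")
  issues <- attr(back, "issues")
  expect_identical(issues$patient_id[issues$severity == "error"], "BAD")

  # corrupt a date textually: row-level error naming the patient
  lines <- readLines(path)
  lines[3] <- sub("2013-03-20", "not-a-date", lines[3])
  writeLines(lines, path)
  expect_warning(back2 <- read_cohort(path), "BAD")
  issues2 <- attr(back2, "issues")
  expect_true(any(grepl("unparseable date", issues2$message) &
                    issues2$patient_id == "BAD"))
})

test_that("write_decisions produces the stable five-column layout", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_decisions(extract_decisions(fixture_cohort)[0, ], path)
  expect_identical(readLines(path),
                   "patient_id,decision_kind,code,rule_id,rationale")

  decisions <- extract_decisions(fixture_cohort)
  # shuffle: ordering on disk must not depend on input order
  write_decisions(decisions[rev(seq_len(nrow(decisions))), ], path)
  lines <- readLines(path)
  expect_length(lines, 139L)
  body <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  expect_identical(body$patient_id, rep(sort(fixture_cohort$patient_id),
                                        each = 2L))
  expect_identical(unique(body$decision_kind[c(TRUE, FALSE)]), "testing")
})
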