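# Synthetic cohorts: the deterministic 69-patient fixture reconstructed from
# the published subgroup counts, the four timing-departure case scenarios,
# and a seeded stochastic simulator for property testing.
#
# The fixture realizes three pathway groups:
#   A (28): EGFR negative, result available before the proteomic order.
#   B (36): EGFR never performed (squamous / no tissue / undocumented).
#   C (5):  proteomic test ordered first; EGFR negative only afterwards.
# Within each group, proteomic result x erlotinib exposure leaves are fixed
# so that every published marginal count is reproduced exactly.

# One row per pathway leaf: group, proteomic result, erlotinib timing
# relative to the proteomic result, and the fixture count (sums to 69).
leaf_table <- function() {
  tibble::tribble(
    ~leaf, ~group, ~vs_result, ~erlotinib, ~n_fixture,
    "A1", "A", "good", "after",  17L,
    "A2", "A", "good", "none",    4L,
    "A3", "A", "poor", "none",    6L,
    "A4", "A", "good", "before",  1L,
    "B1", "B", "good", "after",  15L,
    "B2", "B", "poor", "none",   10L,
    "B3", "B", "good", "none",    8L,
    "B4", "B", "poor", "after",   1L,
    "B5", "B", "good", "before",  1L,
    "B6", "B", "poor", "before",  1L,
    "C1", "C", "good", "after",   3L,
    "C2", "C", "poor", "none",    1L,
    "C3", "C", "good", "none",    1L
  )
}

# Fixture age list: 69 integers frozen from a constraint search so that the
# decade-band counts are 7/31/24/7, range 50-89, the mean rounds to 69.2 and
# the sample SD rounds to 8.5.
FIXTURE_AGES <- c(
  50, 50, 54, 55, 57, 57, 58, 60, 61, 61, 62, 63, 63, 63, 63, 64, 64, 65,
  65, 65, 65, 65, 65, 65, 66, 66, 66, 67, 67, 68, 68, 68, 69, 69, 69, 69,
  69, 69, 70, 70, 70, 70, 70, 70, 72, 72, 72, 72, 72, 73, 74, 74, 75, 75,
  76, 76, 76, 76, 77, 78, 78, 79, 80, 83, 86, 87, 87, 88, 89
)

# Site-of-care labels with fixture counts: 13/12/12/10 for the four
# highest-volume networks (68% of tests) and 22 spread over 7 others.
FIXTURE_VISN_COUNTS <- c(
  "VISN 17" = 13L, "VISN 7" = 12L, "VISN 20" = 12L, "VISN 1" = 10L,
  "VISN 2" = 4L, "VISN 5" = 4L, "VISN 8" = 3L, "VISN 10" = 3L,
  "VISN 12" = 3L, "VISN 16" = 3L, "VISN 22" = 2L
)

#' Build the deterministic 69-patient fixture cohort
#'
#' Reconstructs, patient by patient, a cohort whose every published marginal
#' is reproduced exactly: 33 EGFR-negative and 36 EGFR-not-performed; 50
#' "good" and 19 "poor" proteomic results; 37 treated "good", 13 untreated
#' "good", 2 treated "poor"; 17 squamous / 6 no-tissue / 13 undocumented
#' reasons for missing EGFR tests; 9 patients tested within 90 days of death
#' (3 of them treated, 2 of those "poor"); 10 deceased; and the demographic
#' profile (age bands 7/31/24/7, mean 69.2, SD 8.5; race 48/12/9; 11 care
#' networks with the top four holding 68% of tests; histology
#' 39/20/1/1/8).
#'
#' Dates are deterministic: diagnoses staggered weekly from 2013-01-01, with
#' fixed per-group gaps that realize each leaf's required event ordering.
#' Two "good"/no-erlotinib patients who died near the proteomic order carry a
#' documented justification; they are the records the end-of-life exception
#' (rule X5) reclassifies.
#'
#' @return A 69-row cohort tibble that passes [validate_cohort()] with zero
#'   issues.
#' @export
#' @examples
#' cohort <- build_fixture_cohort()
#' table(cohort$egfr_status)
build_fixture_cohort <- function() {
  leaves <- leaf_table()
  leaf <- rep(leaves$leaf, leaves$n_fixture)
  group <- rep(leaves$group, leaves$n_fixture)
  vs_result <- rep(leaves$vs_result, leaves$n_fixture)
  erl <- rep(leaves$erlotinib, leaves$n_fixture)
  n <- length(leaf)  # 69
  i <- seq_len(n)
  b_index <- ifelse(group == "B", cumsum(group == "B"), NA_integer_)

  # Reasons for missing EGFR tests, assigned positionally within group B.
  no_egfr_reason <- rep("not_applicable", n)
  no_egfr_reason[group == "B"] <-
    rep(c("squamous", "no_tissue", "undocumented"), c(17L, 6L, 13L))

  histology <- rep("adenocarcinoma", n)
  histology[i %in% 1:3] <- "squamous"          # EGFR-tested squamous cases
  histology[i %in% 18:19] <- "unspecified"
  histology[no_egfr_reason == "squamous"] <- "squamous"
  histology[no_egfr_reason == "no_tissue"] <- "unspecified"
  histology[which(b_index == 35L)] <- "mixed"
  histology[which(b_index == 36L)] <- "large_cell_neuroendocrine"

  diagnosis_date <- as.Date("2013-01-01") + (i - 1L) * 7L
  egfr_result_date <- as.Date(rep(NA_character_, n))
  egfr_result_date[group == "A"] <- diagnosis_date[group == "A"] + 30L
  vs_order_date <- diagnosis_date +
    ifelse(group == "A", 60L, ifelse(group == "B", 45L, 30L))
  vs_result_date <- vs_order_date + 14L
  egfr_result_date[group == "C"] <- vs_result_date[group == "C"] + 60L

  erlotinib_start_date <- as.Date(rep(NA_character_, n))
  erlotinib_start_date[erl == "after"] <- vs_result_date[erl == "after"] + 10L
  erlotinib_start_date[erl == "before"] <- vs_order_date[erl == "before"] + 3L
  erlotinib_days_supplied <- rep(NA_integer_, n)
  erlotinib_days_supplied[erl == "after"] <- 60L
  erlotinib_days_supplied[erl == "before"] <- 30L

  # End-of-life set: 9 patients die 60 days after the proteomic order --
  # two untreated "poor" from group A, two untreated "poor" and the two
  # justified "good"/no-erlotinib patients from group B, the three treated
  # near-death patients (one "good", two "poor"). One further death falls
  # well outside the window, for 10 deceased in all.
  eol_idx <- c(22L, 23L,                        # A3 poor, untreated
               which(b_index %in% c(1L, 16L, 17L, 26L, 27L, 34L, 36L)))
  death_date <- as.Date(rep(NA_character_, n))
  death_date[eol_idx] <- vs_order_date[eol_idx] + 60L
  death_date[4L] <- vs_order_date[4L] + 200L    # deceased, beyond the window

  justified <- rep(FALSE, n)
  justified[which(b_index %in% c(26L, 27L))] <- TRUE

  biopsy_performed <- rep(TRUE, n)
  biopsy_performed[which(b_index %in% 18:20)] <- FALSE
  tissue_sufficient <- rep("yes", n)
  tissue_sufficient[which(b_index %in% 18:20)] <- "unknown"
  tissue_sufficient[which(b_index %in% 21:23)] <- "no"
  tissue_sufficient[no_egfr_reason == "undocumented"] <- "unknown"

  cohort <- tibble::tibble(
    patient_id = sprintf("P%03d", i),
    age = as.integer(FIXTURE_AGES),
    race = rep(c("white", "black", "other"), c(48L, 12L, 9L)),
    visn = rep(names(FIXTURE_VISN_COUNTS), FIXTURE_VISN_COUNTS),
    histology = histology,
    diagnosis_date = diagnosis_date,
    death_date = death_date,
    biopsy_performed = biopsy_performed,
    tissue_sufficient = tissue_sufficient,
    egfr_status = ifelse(group == "B", "not_performed", "negative"),
    egfr_result_date = egfr_result_date,
    vs_order_date = vs_order_date,
    vs_result_date = vs_result_date,
    vs_result = vs_result,
    erlotinib_start_date = erlotinib_start_date,
    erlotinib_days_supplied = erlotinib_days_supplied,
    no_egfr_reason = no_egfr_reason,
    treatment_justification_documented = justified
  )
  cohort
}

#' Build the four timing-departure case scenarios
#'
#' Four single-patient records reproducing the published case timelines:
#' \describe{
#'   \item{S1}{Squamous, no EGFR test; erlotinib dispensed as a 3 months'
#'     supply and taken 63 days in all (with a side-effect hold); proteomic
#'     result "poor" about 5 weeks after the restart, after which the drug
#'     was stopped.}
#'   \item{S2}{Adenocarcinoma, no EGFR test; proteomic result "poor" two
#'     weeks after the erlotinib start; drug continued; 28 days (one month's
#'     supply).}
#'   \item{S3}{Squamous, EGFR negative at diagnosis; on progression,
#'     erlotinib and the proteomic test ordered the same day, with the
#'     "good" result returning six weeks later.}
#'   \item{S4}{Adenocarcinoma diagnosed outside the system; proteomic result
#'     "poor"; EGFR ordered only 2 months after that result (negative);
#'     erlotinib never prescribed.}
#' }
#'
#' @return A 4-row cohort tibble (patient IDs `S1`-`S4`).
#' @export
build_scenario_records <- function() {
  dplyr::bind_rows(
    patient_record(
      patient_id = "S1", age = 67L, visn = "VISN 17",
      histology = "squamous", diagnosis_date = "2012-06-04",
      egfr_status = "not_performed", egfr_result_date = NA,
      no_egfr_reason = "squamous",
      erlotinib_start_date = "2014-01-06", erlotinib_days_supplied = 63L,
      # hold after 3 weeks, restart a month later, tested 5 weeks after that
      vs_order_date = "2014-04-02", vs_result_date = "2014-04-09",
      vs_result = "poor"),
    patient_record(
      patient_id = "S2", age = 71L, visn = "VISN 7",
      histology = "adenocarcinoma", diagnosis_date = "2010-05-03",
      egfr_status = "not_performed", egfr_result_date = NA,
      no_egfr_reason = "undocumented", tissue_sufficient = "unknown",
      erlotinib_start_date = "2013-03-04", erlotinib_days_supplied = 28L,
      vs_order_date = "2013-03-11", vs_result_date = "2013-03-18",
      vs_result = "poor"),
    patient_record(
      patient_id = "S3", age = 64L, visn = "VISN 20",
      histology = "squamous", diagnosis_date = "2013-02-04",
      egfr_status = "negative", egfr_result_date = "2013-02-04",
      erlotinib_start_date = "2014-03-03", erlotinib_days_supplied = 30L,
      vs_order_date = "2014-03-03", vs_result_date = "2014-04-14",
      vs_result = "good"),
    patient_record(
      patient_id = "S4", age = 62L, visn = "VISN 1",
      histology = "adenocarcinoma", diagnosis_date = "2014-10-06",
      egfr_status = "negative", egfr_result_date = "2015-03-20",
      vs_order_date = "2015-01-05", vs_result_date = "2015-01-19",
      vs_result = "poor")
  )
}

#' Simulation parameters for stochastic cohorts
#'
#' Defaults are calibrated to the fixture cohort: leaf probabilities are the
#' fixture's 13 pathway-leaf proportions; age-band, race and site weights are
#' the fixture's demographic proportions; the reason split for missing EGFR
#' tests is 17/6/13 squamous/no-tissue/undocumented; and the near-death
#' fraction is 9/69. Event-date gaps are uniform integer-day ranges.
#'
#' @param n_patients Number of patients to simulate (>= 1).
#' @param seed Integer RNG seed; identical parameters and seed reproduce the
#'   cohort exactly.
#' @param leaf_probabilities Named probability vector over the pathway-leaf
#'   labels of the fixture (`A1`..`C3`); must sum to 1.
#' @param age_band_weights Probabilities for the 50-59/60-69/70-79/80-89
#'   decade bands.
#' @param race_weights Named probabilities for white/black/other.
#' @param visn_weights Named probabilities over site-of-care labels.
#' @param egfr_reason_weights Probabilities for the squamous/no-tissue/
#'   undocumented reasons within the EGFR-not-performed group.
#' @param date_ranges List of uniform integer-day ranges: `diagnosis_window`
#'   (two ISO dates), and two-element gap ranges `dx_to_egfr`,
#'   `egfr_to_order`, `dx_to_order`, `order_to_result`, `result_to_egfr`
#'   (group C), `result_to_erl`.
#' @param near_death_fraction Probability a patient dies within the
#'   end-of-life window (90 days) after the proteomic order.
#' @param late_death_fraction Probability of a death beyond that window.
#'
#' @return A list of class `simulation_params`.
#' @export
simulation_params <- function(n_patients,
                              seed = 1L,
                              leaf_probabilities = NULL,
                              age_band_weights = c(7, 31, 24, 7) / 69,
                              race_weights = c(white = 48, black = 12,
                                               other = 9) / 69,
                              visn_weights = FIXTURE_VISN_COUNTS / 69,
                              egfr_reason_weights = c(squamous = 17,
                                                      no_tissue = 6,
                                                      undocumented = 13) / 36,
                              date_ranges = list(
                                diagnosis_window = c("2013-01-01", "2014-06-30"),
                                dx_to_egfr = c(14L, 60L),
                                egfr_to_order = c(1L, 45L),
                                dx_to_order = c(20L, 90L),
                                order_to_result = c(7L, 21L),
                                result_to_egfr = c(7L, 90L),
                                result_to_erl = c(3L, 30L)),
                              near_death_fraction = 9 / 69,
                              late_death_fraction = 1 / 69) {
  if (is.null(leaf_probabilities)) {
    leaves <- leaf_table()
    leaf_probabilities <- stats::setNames(leaves$n_fixture / sum(leaves$n_fixture),
                                          leaves$leaf)
  }
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients < 1L) {
    rlang::abort("n_patients must be a positive integer")
  }
  check_probs <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      rlang::abort(paste0(what, " must be non-negative and sum to 1"))
    }
  }
  check_probs(leaf_probabilities, "leaf_probabilities")
  check_probs(age_band_weights, "age_band_weights")
  check_probs(race_weights, "race_weights")
  check_probs(visn_weights, "visn_weights")
  check_probs(egfr_reason_weights, "egfr_reason_weights")
  if (near_death_fraction + late_death_fraction > 1) {
    rlang::abort("death fractions must sum to at most 1")
  }
  structure(
    list(n_patients = n_patients, seed = as.integer(seed),
         leaf_probabilities = leaf_probabilities,
         age_band_weights = age_band_weights,
         race_weights = race_weights,
         visn_weights = visn_weights,
         egfr_reason_weights = egfr_reason_weights,
         date_ranges = date_ranges,
         near_death_fraction = near_death_fraction,
         late_death_fraction = late_death_fraction),
    class = "simulation_params"
  )
}

runif_days <- function(n, range) {
  as.integer(range[1]) + sample.int(as.integer(range[2]) -
                                      as.integer(range[1]) + 1L, n,
                                    replace = TRUE) - 1L
}

#' Simulate a stochastic patient cohort
#'
#' Draws each patient's pathway leaf, demographics and event dates from the
#' configured distributions. Every generated record satisfies the cohort
#' invariants by construction, and a given parameter set and seed always
#' reproduces the identical cohort.
#'
#' @param params A [simulation_params()].
#' @param keep_leaf If `TRUE`, append the drawn pathway-leaf label as a
#'   `leaf` column (useful for goodness-of-fit checks); the column is not
#'   part of the cohort schema.
#' @return A cohort tibble with `params$n_patients` rows.
#' @export
#' @examples
#' sim <- simulate_cohort(simulation_params(100, seed = 7))
#' nrow(validate_cohort(sim))  # 0
simulate_cohort <- function(params, keep_leaf = FALSE) {
  stopifnot(inherits(params, "simulation_params"))
  withr::with_seed(params$seed, {
    n <- params$n_patients
    dr <- params$date_ranges
    leaves <- leaf_table()
    leaf <- sample(names(params$leaf_probabilities), n, replace = TRUE,
                   prob = params$leaf_probabilities)
    info <- leaves[match(leaf, leaves$leaf), ]
    group <- info$group
    vs_result <- info$vs_result
    erl <- info$erlotinib

    band_lo <- c(50L, 60L, 70L, 80L)
    band <- sample.int(4L, n, replace = TRUE, prob = params$age_band_weights)
    age <- band_lo[band] + sample.int(10L, n, replace = TRUE) - 1L
    race <- sample(names(params$race_weights), n, replace = TRUE,
                   prob = params$race_weights)
    visn <- sample(names(params$visn_weights), n, replace = TRUE,
                   prob = params$visn_weights)

    reason <- rep("not_applicable", n)
    is_b <- group == "B"
    reason[is_b] <- sample(names(params$egfr_reason_weights), sum(is_b),
                           replace = TRUE,
                           prob = params$egfr_reason_weights)
    histology <- rep("adenocarcinoma", n)
    histology[reason == "squamous"] <- "squamous"
    histology[reason == "no_tissue"] <- "unspecified"
    undoc <- reason == "undocumented"
    histology[undoc] <- sample(c("adenocarcinoma", "mixed",
                                 "large_cell_neuroendocrine"),
                               sum(undoc), replace = TRUE,
                               prob = c(0.8, 0.1, 0.1))

    window <- as.Date(dr$diagnosis_window)
    diagnosis_date <- window[1] +
      (sample.int(as.integer(window[2] - window[1]) + 1L, n,
                  replace = TRUE) - 1L)

    egfr_result_date <- as.Date(rep(NA_character_, n))
    vs_order_date <- as.Date(rep(NA_character_, n))
    is_a <- group == "A"
    egfr_result_date[is_a] <- diagnosis_date[is_a] +
      runif_days(sum(is_a), dr$dx_to_egfr)
    vs_order_date[is_a] <- egfr_result_date[is_a] +
      runif_days(sum(is_a), dr$egfr_to_order)
    vs_order_date[!is_a] <- diagnosis_date[!is_a] +
      runif_days(sum(!is_a), dr$dx_to_order)
    vs_result_date <- vs_order_date + runif_days(n, dr$order_to_result)
    is_c <- group == "C"
    egfr_result_date[is_c] <- vs_result_date[is_c] +
      runif_days(sum(is_c), dr$result_to_egfr)

    erlotinib_start_date <- as.Date(rep(NA_character_, n))
    aft <- erl == "after"
    erlotinib_start_date[aft] <- vs_result_date[aft] +
      runif_days(sum(aft), dr$result_to_erl)
    bef <- erl == "before"
    # anywhere from the order date up to the day before the result returns
    gap <- as.integer(vs_result_date[bef] - vs_order_date[bef])
    erlotinib_start_date[bef] <- vs_order_date[bef] +
      floor(stats::runif(sum(bef)) * gap)
    treated <- !is.na(erlotinib_start_date)
    erlotinib_days_supplied <- rep(NA_integer_, n)
    erlotinib_days_supplied[treated] <- sample(c(30L, 60L, 90L), sum(treated),
                                               replace = TRUE)

    u <- stats::runif(n)
    death_date <- as.Date(rep(NA_character_, n))
    near <- u < params$near_death_fraction
    death_date[near] <- vs_order_date[near] + runif_days(sum(near), c(0L, 90L))
    late <- !near & u < params$near_death_fraction + params$late_death_fraction
    death_date[late] <- vs_order_date[late] +
      runif_days(sum(late), c(120L, 400L))

    justified <- vs_result == "good" & !treated & near

    cohort <- tibble::tibble(
      patient_id = sprintf("SIM%05d", seq_len(n)),
      age = age, race = race, visn = visn, histology = histology,
      diagnosis_date = diagnosis_date, death_date = death_date,
      biopsy_performed = reason != "no_tissue",
      tissue_sufficient = ifelse(reason == "no_tissue", "no",
                                 ifelse(reason == "undocumented",
                                        "unknown", "yes")),
      egfr_status = ifelse(is_b, "not_performed", "negative"),
      egfr_result_date = egfr_result_date,
      vs_order_date = vs_order_date, vs_result_date = vs_result_date,
      vs_result = vs_result,
      erlotinib_start_date = erlotinib_start_date,
      erlotinib_days_supplied = erlotinib_days_supplied,
      no_egfr_reason = reason,
      treatment_justification_documented = justified
    )
    if (keep_leaf) cohort$leaf <- leaf
    cohort
  })
}
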