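outcome_cohort <- function(bundle) {
  apply_eligibility(bundle)$cohort
}

test_that("OCS/IV exacerbation rules follow the course-length and month windows", {
  p <- eligible_patient("P1", index = as.Date("2020-03-01"))
  # 2-day course adjacent to a diagnosis: too short to qualify
  p$dispensings <- dplyr::bind_rows(
    p$dispensings,
    tiny_dispensing("P1", "ocs", "2020-05-09", 2, quantity = 60,
                    steroid_compound = "prednisolone"),
    # 10-day course with the diagnosis in the following calendar month
    tiny_dispensing("P1", "ocs", "2020-07-25", 10, quantity = 300,
                    steroid_compound = "prednisolone"))
  p$diagnoses <- dplyr::bind_rows(
    p$diagnoses,
    tibble::tibble(patient_id = "P1", code = "asthma",
                   diagnosis_date = as.Date(c("2020-05-09", "2020-08-03"))))
  b <- bundle_from_patients(p)
  ev <- detect_exacerbations(b, outcome_cohort(b))
  ocs <- ev[ev$event_type == "ocs_iv_course", ]
  expect_equal(nrow(ocs), 1)
  expect_equal(ocs$day, as.numeric(as.Date("2020-07-25") - as.Date("2020-03-01")))
})

test_that("same-type events inside the merge window collapse to one", {
  p <- eligible_patient("P1", index = as.Date("2020-03-01"))
  p$encounters <- tibble::tibble(
    patient_id = "P1", encounter_type = "ed_visit",
    start_date = as.Date(c("2020-06-01", "2020-06-04")),
    end_date = as.Date(c("2020-06-01", "2020-06-04")),
    asthma_related = TRUE, planned = FALSE)
  b <- bundle_from_patients(p)
  ev <- detect_exacerbations(b, outcome_cohort(b), merge_window = 7)
  expect_equal(sum(ev$event_type == "ed_visit"), 1)
  ev2 <- detect_exacerbations(b, outcome_cohort(b), merge_window = 2)
  expect_equal(sum(ev2$event_type == "ed_visit"), 2)
})

test_that("HCRU counts use inclusive stay lengths truncated at the window", {
  p <- eligible_patient("P1", index = as.Date("2020-03-01"))
  b <- bundle_from_patients(p)
  hcru <- summarize_hcru(b, outcome_cohort(b))
  expect_equal(hcru$allcause_admissions, 0)
  expect_equal(hcru$allcause_hospital_days, 0)

  p$encounters <- tibble::tibble(
    patient_id = "P1", encounter_type = "inpatient_admission",
    start_date = as.Date("2020-03-01") + c(10, 360),
    end_date = as.Date("2020-03-01") + c(14, 370),
    asthma_related = c(TRUE, FALSE), planned = FALSE)
  b <- bundle_from_patients(p)
  hcru <- summarize_hcru(b, outcome_cohort(b))
  expect_equal(hcru$allcause_admissions, 2)
  # 10..14 inclusive = 5 days; 360..370 truncated at the boundary = 6 days
  expect_equal(hcru$allcause_hospital_days, 5 + 6)
  expect_equal(hcru$asthma_admissions, 1)
  expect_equal(hcru$asthma_hospital_days, 5)
})

test_that("cost totals respect the biologic flag and asthma attribution", {
  p <- eligible_patient("P1", index = as.Date("2020-03-01"), n_doses = 2)
  # two non-biologic lines in a diagnosis-free month: all-cause only
  p$dispensings <- dplyr::bind_rows(
    p$dispensings,
    tiny_dispensing("P1", "other", "2020-10-05", 1, cost = 1000),
    tiny_dispensing("P1", "other", "2020-10-20", 1, cost = 2500))
  b <- bundle_from_patients(p)
  costs <- summarize_costs(b, outcome_cohort(b))
  expect_equal(costs$allcause_cost_incl, 2 * 100000 + 3500)
  expect_equal(costs$allcause_cost_excl, 3500)
  # biologic lines are asthma-related by definition; the October lines have
  # no asthma diagnosis that month and fall in no admission
  expect_equal(costs$asthma_cost_incl, 2 * 100000)
  expect_equal(costs$asthma_cost_excl, 0)
})

test_that("cost decomposition and attribution bounds hold on generated data", {
  b <- generate_cohort(generator_config(n_patients = 250, seed = 21))
  cohort <- outcome_cohort(b)
  costs <- summarize_costs(b, cohort)
  expect_true(all(costs$asthma_cost_incl <= costs$allcause_cost_incl + 1e-9))
  expect_true(all(costs$asthma_cost_excl <= costs$asthma_cost_incl + 1e-9))
  expect_true(all(costs$allcause_cost_excl <= costs$allcause_cost_incl))
  # exact decomposition: including = excluding + biologic line costs
  bio <- b$dispensings |>
    dplyr::filter(.data$is_biologic) |>
    dplyr::inner_join(cohort, by = "patient_id") |>
    dplyr::mutate(day = as.numeric(.data$dispense_date - .data$index_date)) |>
    dplyr::filter(.data$day >= 0, .data$day < 365) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(bio_cost = sum(.data$cost))
  j <- dplyr::left_join(costs, bio, by = "patient_id") |>
    dplyr::mutate(bio_cost = tidyr::replace_na(.data$bio_cost, 0))
  expect_equal(j$allcause_cost_incl - j$allcause_cost_excl, j$bio_cost)
})

test_that("every admission-type exacerbation appears in asthma HCRU counts", {
  b <- generate_cohort(generator_config(n_patients = 200, seed = 22))
  cohort <- outcome_cohort(b)
  ev <- detect_exacerbations(b, cohort)
  hcru <- summarize_hcru(b, cohort)
  adm <- ev |>
    dplyr::filter(.data$event_type == "hospital_admission") |>
    dplyr::count(.data$patient_id)
  j <- dplyr::left_join(adm, hcru, by = "patient_id")
  expect_true(all(j$n <= j$asthma_admissions))
})

test_that("steroid exposure converts to prednisone equivalents", {
  p <- eligible_patient("P1", index = as.Date("2020-03-01"))
  b <- bundle_from_patients(p)
  cohort <- outcome_cohort(b)
  st <- steroid_exposure(b, cohort)
  expect_equal(st$steroid_cumulative_mg, 0)
  expect_equal(st$steroid_daily_avg_mg, 0)
  expect_false(st$steroid_any_use)

  p$dispensings <- dplyr::bind_rows(
    p$dispensings,
    # 5 days x 40 mg prednisolone
    tiny_dispensing("P1", "ocs", "2020-06-01", 5, quantity = 200,
                    steroid_compound = "prednisolone"),
    # 4 mg methylprednisolone x 1 day -> 5 mg prednisone equivalent
    tiny_dispensing("P1", "iv_steroid", "2020-07-01", 1, quantity = 4,
                    steroid_compound = "methylprednisolone"))
  b <- bundle_from_patients(p)
  st <- steroid_exposure(b, outcome_cohort(b))
  expect_equal(st$steroid_cumulative_mg, 200 + 5)
  expect_equal(st$steroid_daily_avg_mg, 205 / 6)
  expect_true(st$steroid_any_use)

  p$dispensings$steroid_compound[
    p$dispensings$drug_code == "iv_steroid"] <- NA
  b <- bundle_from_patients(p)
  expect_warning(st <- steroid_exposure(b, outcome_cohort(b)),
                 "without a known compound")
  expect_equal(st$steroid_cumulative_mg, 200)
})

test_that("stratified summaries report relative differences vs the reference", {
  tbl <- tibble::tibble(patient_id = sprintf("P%d", 1:40),
                        n_ed = c(rep(0.14, 20), rep(0.28, 20)))
  groups <- rep(c("adherent", "discontinuation"), each = 20)
  out <- stratify_outcomes(tbl, groups, outcomes = "n_ed")
  ref <- out[out$group == "adherent", ]
  expect_true(ref$is_reference)
  expect_equal(ref$pct_diff_vs_ref, 0)
  expect_equal(out$pct_diff_vs_ref[out$group == "discontinuation"], 100)

  # single group: reference relative difference is 0
  one <- stratify_outcomes(tbl, rep("adherent", 40), outcomes = "n_ed")
  expect_equal(one$pct_diff_vs_ref, 0)

  # zero reference mean: undefined, flagged
  tbl$n_ed[1:20] <- 0
  out <- stratify_outcomes(tbl, groups, outcomes = "n_ed")
  disc <- out[out$group == "discontinuation", ]
  expect_true(is.na(disc$pct_diff_vs_ref))
  expect_true(disc$undefined_ref)
})

test_that("the outcome table assembles one complete row per patient", {
  b <- generate_cohort(generator_config(n_patients = 80, seed = 23))
  cohort <- outcome_cohort(b)
  out <- build_outcome_table(b, cohort)
  expect_equal(nrow(out), nrow(cohort))
  expect_true(all(c("exac_hospital_admission", "exac_ed_visit",
                    "exac_ocs_iv_course", "exac_total",
                    "allcause_cost_incl", "steroid_cumulative_mg") %in%
                    names(out)))
  expect_false(anyNA(out$exac_total))
  expect_true(all(out$exac_total >= 0))
})
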