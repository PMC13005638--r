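# Small hand-built claims fixtures used across the IO, cohort and outcome
# tests. Dates are chosen so patient "A01" is a clean eligible mepolizumab
# initiator (index 2020-03-01).

tiny_patients <- function() {
  tibble::tibble(
    patient_id = c("A01", "B02"),
    birth_year = c(1960L, 1985L),
    sex = c("female", "male"),
    enrollment_start = as.Date(c("2018-01-01", "2019-06-01")),
    enrollment_end = as.Date(c("2021-12-31", "2021-12-31")),
    smoking_status = c("never", "unknown"))
}

tiny_dispensing <- function(patient_id, drug_code, date, days_supplied = 0L,
                            quantity = 1, cost = 1000,
                            steroid_compound = "none") {
  tibble::tibble(
    patient_id = patient_id, drug_code = drug_code,
    dispense_date = as.Date(date), days_supplied = as.integer(days_supplied),
    quantity = quantity, cost = cost,
    is_biologic = drug_code %in% adheretraj::asthma_biologics,
    steroid_compound = steroid_compound)
}

tiny_bundle <- function() {
  dispensings <- dplyr::bind_rows(
    tiny_dispensing("A01", "ics_laba", "2019-12-15", 30, cost = 4000),
    tiny_dispensing("A01", "mepolizumab", "2020-03-01", cost = 160000),
    tiny_dispensing("A01", "mepolizumab", "2020-03-29", cost = 160000),
    tiny_dispensing("A01", "ocs", "2020-05-10", 7, quantity = 210,
                    cost = 800, steroid_compound = "prednisolone"),
    tiny_dispensing("B02", "ics_laba", "2020-01-10", 30, cost = 4000))
  diagnoses <- tibble::tibble(
    patient_id = c("A01", "A01", "B02"),
    code = c("asthma", "asthma", "asthma"),
    diagnosis_date = as.Date(c("2019-12-20", "2020-05-10", "2020-01-10")))
  encounters <- tibble::tibble(
    patient_id = c("A01", "A01"),
    encounter_type = c("inpatient_admission", "ed_visit"),
    start_date = as.Date(c("2020-06-10", "2020-08-01")),
    end_date = as.Date(c("2020-06-14", "2020-08-01")),
    asthma_related = c(TRUE, TRUE),
    planned = c(FALSE, FALSE))
  adheretraj::claims_bundle(tiny_patients(), dispensings, diagnoses,
                            encounters)
}

# minimal per-patient bundle builder for eligibility tests: one biologic
# initiator with configurable history
eligible_patient <- function(id = "P1", biologic = "mepolizumab",
                             index = as.Date("2020-03-01"), birth_year = 1970L,
                             dx_offset = -60, extra_dx = NULL,
                             enroll_start_offset = -120,
                             enroll_end_offset = 400,
                             n_doses = 13, dose_interval = 28) {
  doses <- index + seq(0, by = dose_interval, length.out = n_doses)
  dispensings <- dplyr::bind_rows(
    tiny_dispensing(id, "ics_laba", index + dx_offset - 10, 30),
    tiny_dispensing(id, biologic, doses, cost = 100000))
  diagnoses <- tibble::tibble(patient_id = id, code = "asthma",
                              diagnosis_date = index + dx_offset)
  if (!is.null(extra_dx)) {
    diagnoses <- dplyr::bind_rows(diagnoses, extra_dx)
  }
  patients <- tibble::tibble(
    patient_id = id, birth_year = birth_year, sex = "female",
    enrollment_start = index + enroll_start_offset,
    enrollment_end = index + enroll_end_offset,
    smoking_status = "never")
  list(patients = patients, dispensings = dispensings, diagnoses = diagnoses)
}

bundle_from_patients <- function(...) {
  parts <- list(...)
  empty_enc <- tibble::tibble(
    patient_id = character(), encounter_type = character(),
    start_date = as.Date(character()), end_date = as.Date(character()),
    asthma_related = logical(), planned = logical())
  adheretraj::claims_bundle(
    dplyr::bind_rows(purrr::map(parts, "patients")),
    dplyr::bind_rows(purrr::map(parts, "dispensings")),
    dplyr::bind_rows(purrr::map(parts, "diagnoses")),
    dplyr::bind_rows(purrr::map(parts, "encounters")) |>
      (\(x) if (nrow(x)) x else empty_enc)())
}
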