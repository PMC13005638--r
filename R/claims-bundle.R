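# Claims data model: four linked tables (patients, dispensings, diagnoses,
# encounters) with a small controlled vocabulary standing in for proprietary
# code systems. All dates are calendar dates; analysis modules convert to
# integer day offsets from each patient's index date.

#' Controlled vocabularies of the claims schema
#'
#' The five asthma biologics, the drug classes the eligibility and outcome
#' rules need, the diagnosis labels (asthma plus each exclusion condition),
#' and the corticosteroid compounds with defined prednisone equivalents.
#' Real code systems (e.g. local receipt or disease codes) are expected to be
#' mapped onto these semantic labels before `read_bundle()`.
#'
#' @format Character vectors.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
asthma_biologics <- c("benralizumab", "dupilumab", "mepolizumab",
                      "omalizumab", "tezepelumab")

#' @rdname vocabularies
#' @export
drug_codes <- c(asthma_biologics, "ics", "laba", "ics_laba", "lama",
                "ocs", "iv_steroid", "other")

#' @rdname vocabularies
#' @export
diagnosis_codes <- c("asthma", "lung_malignancy", "tuberculosis",
                     "cystic_fibrosis", "hypereosinophilic_syndrome", "egpa",
                     "chronic_spontaneous_urticaria", "atopic_dermatitis",
                     "prurigo_nodularis", "seasonal_allergic_rhinitis",
                     "crs_nasal_polyps", "other")

#' @rdname vocabularies
#' @export
steroid_compounds <- c("prednisolone", "methylprednisolone", "hydrocortisone",
                       "dexamethasone", "none")

#' Adherence category labels, in decreasing adherence order
#' @export
adherence_categories <- c("adherent", "partially_adherent",
                          "minimally_adherent", "discontinuation")

bundle_schemas <- list(
  patients = c(patient_id = "character", birth_year = "integer",
               sex = "character", enrollment_start = "Date",
               enrollment_end = "Date", smoking_status = "character"),
  dispensings = c(patient_id = "character", drug_code = "character",
                  dispense_date = "Date", days_supplied = "integer",
                  quantity = "numeric", cost = "numeric",
                  is_biologic = "logical", steroid_compound = "character"),
  diagnoses = c(patient_id = "character", code = "character",
                diagnosis_date = "Date"),
  encounters = c(patient_id = "character", encounter_type = "character",
                 start_date = "Date", end_date = "Date",
                 asthma_related = "logical", planned = "logical")
)

#' Assemble a claims bundle
#'
#' Bundles the four claims tables into a single object that all pipeline
#' stages consume. Column presence and types are checked eagerly; value-level
#' invariants are reported by [validate_bundle()].
#'
#' @param patients,dispensings,diagnoses,encounters Data frames following the
#'   documented schema (see [read_bundle()] for the file layout).
#' @param validate If `TRUE` (default), abort when [validate_bundle()] finds
#'   any violation.
#' @return An object of class `claims_bundle`: a named list of four tibbles.
#' @export
claims_bundle <- function(patients, dispensings, diagnoses, encounters,
                          validate = TRUE) {
  tables <- list(patients = patients, dispensings = dispensings,
                 diagnoses = diagnoses, encounters = encounters)
  tables <- purrr::imap(tables, function(tbl, name) {
    tbl <- tibble::as_tibble(tbl)
    schema <- bundle_schemas[[name]]
    missing <- setdiff(names(schema), names(tbl))
    if (length(missing)) {
      abort(sprintf("table '%s' is missing column(s): %s",
                    name, paste(missing, collapse = ", ")))
    }
    extra <- setdiff(names(tbl), names(schema))
    if (length(extra)) {
      abort(sprintf("table '%s' has unknown column(s): %s",
                    name, paste(extra, collapse = ", ")))
    }
    tbl[names(schema)]
  })
  bundle <- structure(tables, class = "claims_bundle")
  if (validate) {
    report <- validate_bundle(bundle)
    if (nrow(report)) {
      abort(c("claims bundle failed validation",
              utils::capture.output(print(report, n = 10))),
            report = report)
    }
  }
  bundle
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("<claims_bundle>\n")
  for (name in names(x)) {
    cat(sprintf("  %-12s %6d rows\n", name, nrow(x[[name]])))
  }
  invisible(x)
}

violation <- function(table, row, rule, message) {
  tibble::tibble(table = table, row = as.integer(row), rule = rule,
                 message = message)
}

check_rule <- function(bad, table, rule, message) {
  idx <- which(bad)
  if (!length(idx)) return(NULL)
  violation(table, idx, rule, message)
}

#' Validate a claims bundle
#'
#' Checks every typed invariant of the schema: vocabulary membership, interval
#' ordering, non-negative costs/supplies, the biologic flag consistency, the
#' single-day unplanned nature of ED encounters, patient id uniqueness, and
#' referential integrity of the child tables. Violations are data, not
#' exceptions: the return value is a tibble with one row per violation.
#'
#' @param bundle A `claims_bundle`.
#' @return A tibble with columns `table`, `row`, `rule`, `message`; zero rows
#'   iff the bundle is valid.
#' @export
validate_bundle <- function(bundle) {
  p <- bundle$patients; d <- bundle$dispensings
  dx <- bundle$diagnoses; e <- bundle$encounters
  out <- list(
    check_rule(is.na(p$patient_id) | p$patient_id == "", "patients",
               "patient_id_present", "patient_id must be non-empty"),
    check_rule(duplicated(p$patient_id), "patients", "patient_id_unique",
               "duplicate patient_id"),
    check_rule(!p$sex %in% c("male", "female"), "patients", "sex_vocabulary",
               "sex must be male or female"),
    check_rule(!p$smoking_status %in% c("current_former", "never", "unknown"),
               "patients", "smoking_vocabulary",
               "smoking_status outside vocabulary"),
    check_rule(is.na(p$enrollment_start) | is.na(p$enrollment_end) |
                 p$enrollment_start > p$enrollment_end, "patients",
               "enrollment_order",
               "enrollment_start must be <= enrollment_end"),
    check_rule(!d$drug_code %in% drug_codes, "dispensings",
               "drug_vocabulary", "drug_code outside vocabulary"),
    check_rule(is.na(d$cost) | d$cost < 0, "dispensings", "cost_nonnegative",
               "cost must be >= 0"),
    check_rule(is.na(d$days_supplied) | d$days_supplied < 0, "dispensings",
               "days_supplied_nonnegative", "days_supplied must be >= 0"),
    check_rule(is.na(d$is_biologic) |
                 xor(d$is_biologic, d$drug_code %in% asthma_biologics),
               "dispensings", "biologic_flag",
               "is_biologic must be true iff drug_code is one of the five biologics"),
    check_rule(!(is.na(d$steroid_compound) |
                   d$steroid_compound %in% steroid_compounds),
               "dispensings", "steroid_vocabulary",
               "steroid_compound outside vocabulary"),
    check_rule(!d$patient_id %in% p$patient_id, "dispensings",
               "patient_exists", "dispensing for unknown patient"),
    check_rule(!dx$code %in% diagnosis_codes, "diagnoses",
               "diagnosis_vocabulary", "diagnosis code outside vocabulary"),
    check_rule(!dx$patient_id %in% p$patient_id, "diagnoses",
               "patient_exists", "diagnosis for unknown patient"),
    check_rule(!e$encounter_type %in% c("inpatient_admission", "ed_visit"),
               "encounters", "encounter_vocabulary",
               "encounter_type outside vocabulary"),
    check_rule(is.na(e$start_date) | is.na(e$end_date) |
                 e$start_date > e$end_date, "encounters", "date_order",
               "start_date must be <= end_date"),
    check_rule(e$encounter_type == "ed_visit" & e$start_date != e$end_date,
               "encounters", "ed_single_day",
               "ED visits must have end_date equal to start_date"),
    check_rule(e$encounter_type == "ed_visit" &
                 (is.na(e$planned) | e$planned), "encounters",
               "ed_not_planned", "ED visits must have planned = FALSE"),
    check_rule(!e$patient_id %in% p$patient_id, "encounters",
               "patient_exists", "encounter for unknown patient")
  )
  out <- dplyr::bind_rows(out)
  if (!nrow(out)) {
    out <- tibble::tibble(table = character(), row = integer(),
                          rule = character(), message = character())
  }
  dplyr::arrange(out, .data$table, .data$row)
}
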