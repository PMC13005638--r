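# Outcome phenotyping over the 12-month follow-up: exacerbations of three
# types (asthma admissions, asthma ED visits, qualifying oral/IV
# corticosteroid courses), all-cause and asthma-related HCRU, pharmacy costs
# with and without biologic lines, and corticosteroid exposure in prednisone
# equivalents.

prednisone_equivalents <- c(prednisolone = 1, methylprednisolone = 1.25,
                            hydrocortisone = 0.25, dexamethasone = 6.67)

# day offsets of one table's date column relative to each patient's index
with_offsets <- function(tbl, cohort, date_col) {
  tbl |>
    dplyr::inner_join(cohort[c("patient_id", "index_date")],
                      by = "patient_id") |>
    dplyr::mutate(day = as.numeric(.data[[date_col]] - .data$index_date))
}

merge_close_events <- function(days, window) {
  days <- sort(days)
  if (length(days) <= 1) return(days)
  # chain: an event is merged into the last *kept* event, not its neighbour
  out <- days[1]
  last <- days[1]
  for (d in days[-1]) {
    if (d - last > window) {
      out <- c(out, d)
      last <- d
    }
  }
  out
}

#' Detect exacerbation events
#'
#' Exacerbations are asthma-related hospital admissions, asthma-related ED
#' visits, or qualifying oral/IV corticosteroid courses: OCS dispensings
#' lasting 3 to 28 days dispensed within the calendar month of, or the month
#' before, an asthma diagnosis month; and IV steroid dispensings in the
#' month of or the month before an asthma diagnosis (the open-ended "prior"
#' is bounded to one month, mirroring the OCS look-back). Same-type events
#' closer than `merge_window` days are merged into one.
#'
#' @param bundle A `claims_bundle`.
#' @param cohort Cohort tibble with `patient_id`, `index_date`.
#' @param config An [engine_config()] (for the follow-up window).
#' @param merge_window Same-type merge window in days (default 7).
#' @param ocs_min_days,ocs_max_days Qualifying OCS course duration bounds.
#' @return A tibble of events: `patient_id`, `event_type`
#'   (`hospital_admission`, `ed_visit`, `ocs_iv_course`), `day`.
#' @export
detect_exacerbations <- function(bundle, cohort, config = engine_config(),
                                 merge_window = 7, ocs_min_days = 3,
                                 ocs_max_days = 28) {
  followup <- config$followup_days
  enc <- with_offsets(bundle$encounters, cohort, "start_date") |>
    dplyr::filter(.data$asthma_related, .data$day >= 0, .data$day < followup)
  admissions <- enc |>
    dplyr::filter(.data$encounter_type == "inpatient_admission") |>
    dplyr::transmute(.data$patient_id, event_type = "hospital_admission",
                     .data$day)
  ed <- enc |>
    dplyr::filter(.data$encounter_type == "ed_visit") |>
    dplyr::transmute(.data$patient_id, event_type = "ed_visit", .data$day)

  asthma_months <- bundle$diagnoses |>
    dplyr::filter(.data$code == "asthma") |>
    dplyr::transmute(.data$patient_id, dx_month = month_key(.data$diagnosis_date)) |>
    dplyr::distinct()
  steroid <- with_offsets(bundle$dispensings, cohort, "dispense_date") |>
    dplyr::filter(.data$day >= 0, .data$day < followup) |>
    dplyr::filter((.data$drug_code == "ocs" &
                     .data$days_supplied >= ocs_min_days &
                     .data$days_supplied <= ocs_max_days) |
                    .data$drug_code == "iv_steroid") |>
    dplyr::mutate(disp_month = month_key(.data$dispense_date)) |>
    dplyr::inner_join(asthma_months, by = "patient_id",
                      relationship = "many-to-many") |>
    dplyr::filter((.data$dx_month - .data$disp_month) %in% c(0L, 1L)) |>
    dplyr::distinct(.data$patient_id, .data$day) |>
    dplyr::mutate(event_type = "ocs_iv_course")

  dplyr::bind_rows(admissions, ed, steroid[c("patient_id", "event_type", "day")]) |>
    dplyr::group_by(.data$patient_id, .data$event_type) |>
    dplyr::reframe(day = merge_close_events(.data$day, merge_window)) |>
    dplyr::arrange(.data$patient_id, .data$event_type, .data$day)
}

#' Summarize healthcare resource utilization
#'
#' Counts hospital admissions (inpatient encounters starting inside the
#' follow-up window), in-hospital days (inclusive of both endpoints,
#' truncated at the window boundary), and ED visits, both all-cause and
#' restricted to asthma-related encounters.
#'
#' @inheritParams detect_exacerbations
#' @return One row per cohort patient with `allcause_admissions`,
#'   `allcause_hospital_days`, `allcause_ed_visits` and their
#'   `asthma_`-prefixed counterparts.
#' @export
summarize_hcru <- function(bundle, cohort, config = engine_config()) {
  followup <- config$followup_days
  enc <- with_offsets(bundle$encounters, cohort, "start_date") |>
    dplyr::mutate(end_day = as.numeric(.data$end_date - .data$index_date)) |>
    dplyr::filter(.data$day >= 0, .data$day < followup)
  roll <- function(e, prefix) {
    e |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(
        admissions = sum(.data$encounter_type == "inpatient_admission"),
        hospital_days = sum(ifelse(
          .data$encounter_type == "inpatient_admission",
          pmin(.data$end_day, followup) - .data$day + 1, 0)),
        ed_visits = sum(.data$encounter_type == "ed_visit"),
        .groups = "drop") |>
      dplyr::rename_with(~ paste0(prefix, "_", .x), -"patient_id")
  }
  out <- cohort["patient_id"] |>
    dplyr::left_join(roll(enc, "allcause"), by = "patient_id") |>
    dplyr::left_join(roll(dplyr::filter(enc, .data$asthma_related), "asthma"),
                     by = "patient_id")
  dplyr::mutate(out, dplyr::across(-"patient_id", ~ tidyr::replace_na(.x, 0)))
}

#' Summarize pharmacy costs
#'
#' All-cause cost is the sum of all dispensing costs inside the follow-up
#' window. A line is asthma-related when an asthma diagnosis exists in the
#' same calendar month (the outpatient linkage available in claims) or when
#' it falls within an asthma-related admission (between the admission and
#' discharge dates); biologic lines are asthma-related by definition. Each
#' total is reported including and excluding biologic lines.
#'
#' @inheritParams detect_exacerbations
#' @return One row per cohort patient: `allcause_cost_incl`,
#'   `allcause_cost_excl`, `asthma_cost_incl`, `asthma_cost_excl` (JPY).
#' @export
summarize_costs <- function(bundle, cohort, config = engine_config()) {
  followup <- config$followup_days
  disp <- with_offsets(bundle$dispensings, cohort, "dispense_date") |>
    dplyr::filter(.data$day >= 0, .data$day < followup) |>
    dplyr::mutate(disp_month = month_key(.data$dispense_date))
  asthma_months <- bundle$diagnoses |>
    dplyr::filter(.data$code == "asthma") |>
    dplyr::transmute(.data$patient_id,
                     disp_month = month_key(.data$diagnosis_date)) |>
    dplyr::distinct() |>
    dplyr::mutate(month_flag = TRUE)
  asthma_stays <- bundle$encounters |>
    dplyr::filter(.data$encounter_type == "inpatient_admission",
                  .data$asthma_related)
  in_stay <- disp |>
    dplyr::inner_join(asthma_stays[c("patient_id", "start_date", "end_date")],
                      by = "patient_id", relationship = "many-to-many") |>
    dplyr::filter(.data$dispense_date >= .data$start_date,
                  .data$dispense_date <= .data$end_date) |>
    dplyr::distinct(.data$patient_id, .data$dispense_date) |>
    dplyr::mutate(stay_flag = TRUE)
  disp <- disp |>
    dplyr::left_join(asthma_months, by = c("patient_id", "disp_month")) |>
    dplyr::left_join(in_stay, by = c("patient_id", "dispense_date"),
                     relationship = "many-to-one") |>
    dplyr::mutate(asthma_rel = .data$is_biologic |
                    !is.na(.data$month_flag) | !is.na(.data$stay_flag))
  totals <- disp |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      allcause_cost_incl = sum(.data$cost),
      allcause_cost_excl = sum(.data$cost[!.data$is_biologic]),
      asthma_cost_incl = sum(.data$cost[.data$asthma_rel]),
      asthma_cost_excl = sum(.data$cost[.data$asthma_rel & !.data$is_biologic]),
      .groups = "drop")
  out <- dplyr::left_join(cohort["patient_id"], totals, by = "patient_id")
  dplyr::mutate(out, dplyr::across(-"patient_id", ~ tidyr::replace_na(.x, 0)))
}

#' Oral and IV corticosteroid exposure in prednisone equivalents
#'
#' Converts each OCS / IV steroid dispensing (with `quantity` in mg of the
#' dispensed compound) to prednisone-equivalent mg (prednisolone 1:1,
#' methylprednisolone x1.25, hydrocortisone x0.25, dexamethasone x6.67).
#' Cumulative exposure is the sum over the window; the daily average is the
#' cumulative amount divided by the number of distinct exposed days (days
#' covered by a steroid course), not by the window length. Rows with an
#' unknown compound are skipped with a warning.
#'
#' @inheritParams detect_exacerbations
#' @return One row per cohort patient: `steroid_cumulative_mg`,
#'   `steroid_daily_avg_mg`, `steroid_any_use`.
#' @export
steroid_exposure <- function(bundle, cohort, config = engine_config()) {
  followup <- config$followup_days
  rows <- with_offsets(bundle$dispensings, cohort, "dispense_date") |>
    dplyr::filter(.data$drug_code %in% c("ocs", "iv_steroid"),
                  .data$day >= 0, .data$day < followup)
  unknown <- is.na(rows$steroid_compound) | rows$steroid_compound == "none" |
    !rows$steroid_compound %in% names(prednisone_equivalents)
  if (any(unknown)) {
    warn(sprintf("skipping %d steroid row(s) without a known compound",
                 sum(unknown)))
    rows <- rows[!unknown, ]
  }
  per_patient <- rows |>
    dplyr::mutate(mg = .data$quantity *
                    prednisone_equivalents[.data$steroid_compound]) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      steroid_cumulative_mg = sum(.data$mg),
      exposed_days = length(unique(unlist(purrr::map2(
        .data$day, pmax(.data$days_supplied, 1),
        function(d, s) seq(d, min(d + s - 1, followup - 1)))))),
      .groups = "drop") |>
    dplyr::mutate(steroid_daily_avg_mg =
                    .data$steroid_cumulative_mg / .data$exposed_days)
  cohort["patient_id"] |>
    dplyr::left_join(per_patient, by = "patient_id") |>
    dplyr::mutate(
      steroid_cumulative_mg = tidyr::replace_na(.data$steroid_cumulative_mg, 0),
      steroid_daily_avg_mg = tidyr::replace_na(.data$steroid_daily_avg_mg, 0),
      steroid_any_use = !is.na(.data$exposed_days) & .data$exposed_days > 0) |>
    dplyr::select(-"exposed_days")
}

#' Per-patient outcome table
#'
#' Joins exacerbation counts by type, HCRU, pharmacy costs and steroid
#' exposure into one row per cohort patient.
#'
#' @inheritParams detect_exacerbations
#' @return A tibble, one row per patient.
#' @export
build_outcome_table <- function(bundle, cohort, config = engine_config(),
                                merge_window = 7) {
  events <- detect_exacerbations(bundle, cohort, config, merge_window)
  counts <- events |>
    dplyr::count(.data$patient_id, .data$event_type) |>
    tidyr::pivot_wider(names_from = "event_type", values_from = "n",
                       values_fill = 0L,
                       names_prefix = "exac_")
  for (col in c("exac_hospital_admission", "exac_ed_visit",
                "exac_ocs_iv_course")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  out <- cohort["patient_id"] |>
    dplyr::left_join(counts, by = "patient_id") |>
    dplyr::mutate(dplyr::across(dplyr::starts_with("exac_"),
                                ~ tidyr::replace_na(.x, 0L)),
                  exac_total = .data$exac_hospital_admission +
                    .data$exac_ed_visit + .data$exac_ocs_iv_course) |>
    dplyr::left_join(summarize_hcru(bundle, cohort, config),
                     by = "patient_id") |>
    dplyr::left_join(summarize_costs(bundle, cohort, config),
                     by = "patient_id") |>
    dplyr::left_join(steroid_exposure(bundle, cohort, config),
                     by = "patient_id")
  out
}

#' Stratify outcomes by adherence group
#'
#' Summarizes each outcome column by group (adherence category or trajectory
#' cluster label) and reports the relative mean difference versus the
#' reference group, \eqn{(\bar{x}_g - \bar{x}_{ref}) / \bar{x}_{ref} \times
#' 100}. A zero reference mean makes the relative difference undefined
#' (`NA`, flagged).
#'
#' @param outcome_table Output of [build_outcome_table()] (or any per-patient
#'   tibble of outcomes).
#' @param groups A vector (or per-patient tibble column) of group labels
#'   aligned with `outcome_table` rows.
#' @param outcomes Character vector of outcome columns to summarize
#'   (default: all numeric columns).
#' @param reference Reference group; defaults to `"adherent"` when present,
#'   else `"A"` when present, else the first group.
#' @return A long tibble: `group`, `outcome`, `n`, `mean`, `pct_diff_vs_ref`,
#'   `is_reference`, `undefined_ref`.
#' @export
stratify_outcomes <- function(outcome_table, groups, outcomes = NULL,
                              reference = NULL) {
  stopifnot(length(groups) == nrow(outcome_table))
  if (is.null(outcomes)) {
    outcomes <- names(outcome_table)[purrr::map_lgl(outcome_table, is.numeric)]
  }
  if (is.null(reference)) {
    reference <- if ("adherent" %in% groups) "adherent"
    else if ("A" %in% groups) "A" else sort(unique(groups))[1]
  }
  long <- outcome_table |>
    dplyr::mutate(.group = groups) |>
    tidyr::pivot_longer(dplyr::all_of(outcomes), names_to = "outcome",
                        values_to = "value") |>
    dplyr::group_by(group = .data$.group, .data$outcome) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     .groups = "drop")
  ref <- long |>
    dplyr::filter(.data$group == reference) |>
    dplyr::select("outcome", ref_mean = "mean")
  long |>
    dplyr::left_join(ref, by = "outcome") |>
    dplyr::mutate(
      is_reference = .data$group == reference,
      undefined_ref = .data$ref_mean == 0 & .data$mean != .data$ref_mean,
      pct_diff_vs_ref = ifelse(.data$ref_mean == 0,
                               ifelse(.data$mean == 0, 0, NA_real_),
                               100 * (.data$mean - .data$ref_mean) /
                                 .data$ref_mean)) |>
    dplyr::select("group", "outcome", "n", "mean", "pct_diff_vs_ref",
                  "is_reference", "undefined_ref") |>
    dplyr::arrange(.data$outcome, .data$group)
}
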