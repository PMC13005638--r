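# The core adherence computation: dosing-schedule tracking with the dynamic
# 7-day buffer, possession coverage and MPR, the binary per-bin adherence
# series, and the four-category gap/dose-count classifier.

#' Adherence engine configuration
#'
#' @param buffer_days Dynamic buffer around the expected dose date within
#'   which a dose counts as on schedule (default 7, i.e. +/- 7 days).
#' @param followup_days Length of the assessment window starting at the index
#'   dose (default 365, the 12-month follow-up).
#' @param bin_days Width of the bins of the binary adherence series (default
#'   28 days, aligned with the Q4W cycle: 13 bins over 12 months; the final
#'   365th day is ignored).
#' @param coverage_threshold Fraction of a bin that must be possession-covered
#'   for the bin to count as adherent. The default 0.5 (a majority of the
#'   bin's days) tolerates the benign schedule drift the +/- 7-day buffer
#'   permits while still flagging every missed dose; set to 1 for a strict
#'   full-coverage rule.
#' @return An `engine_config` list.
#' @export
engine_config <- function(buffer_days = 7, followup_days = 365, bin_days = 28,
                          coverage_threshold = 0.5) {
  stopifnot(buffer_days >= 0, followup_days > 0, bin_days > 0,
            coverage_threshold > 0, coverage_threshold <= 1)
  structure(list(buffer_days = buffer_days, followup_days = followup_days,
                 bin_days = bin_days, n_bins = followup_days %/% bin_days,
                 coverage_threshold = coverage_threshold),
            class = "engine_config")
}

prepare_doses <- function(dose_dates) {
  dose_dates <- sort(dose_dates)
  if (anyDuplicated(dose_dates)) {
    warn("duplicate dose dates collapsed to single doses")
    dose_dates <- unique(dose_dates)
  }
  dose_dates
}

#' Track the dosing schedule with a dynamic buffer
#'
#' The expected date of dose k+1 is the actual date of dose k plus that
#' phase's interval: the schedule is dynamically reset at every taken dose. A
#' dose is on schedule when it falls within `buffer_days` of its expected
#' date; the first (index) dose anchors the schedule and is on schedule by
#' definition.
#'
#' @param dose_dates Numeric day offsets from the index date (first must be 0).
#' @param regimen A [dosing_regimen()].
#' @param config An [engine_config()].
#' @return A tibble with one row per dose: `dose`, `date`, `expected`,
#'   `on_schedule`.
#' @examples
#' track_schedule(c(0, 22), dosing_regimen("dupilumab"))
#' @export
track_schedule <- function(dose_dates, regimen, config = engine_config()) {
  dose_dates <- prepare_doses(dose_dates)
  if (!length(dose_dates)) abort("at least one dose (the index dose) required")
  regimen <- resolve_regimen(regimen, dose_dates)
  n <- length(dose_dates)
  expected <- c(dose_dates[1],
                if (n > 1) dose_dates[-n] + interval_at(regimen, seq_len(n - 1)))
  on_schedule <- abs(dose_dates - expected) <= config$buffer_days
  tibble::tibble(dose = seq_len(n), date = dose_dates, expected = expected,
                 on_schedule = on_schedule)
}

#' Possession-covered day intervals
#'
#' Each dose confers possession for its expected phase interval (the natural
#' supply proxy for single-administration injectables): dose k covers
#' `[date_k, date_k + interval_k)`. Overlapping intervals are unioned and
#' coverage is truncated at the end of follow-up.
#'
#' @inheritParams track_schedule
#' @return A tibble of half-open covered intervals (`start`, `end`), in days.
#' @export
coverage_intervals <- function(dose_dates, regimen, config = engine_config()) {
  dose_dates <- prepare_doses(dose_dates)
  if (!length(dose_dates)) {
    return(tibble::tibble(start = numeric(), end = numeric()))
  }
  regimen <- resolve_regimen(regimen, dose_dates)
  n <- length(dose_dates)
  start <- dose_dates
  end <- pmin(dose_dates + interval_at(regimen, seq_len(n)),
              config$followup_days)
  keep <- start < config$followup_days & end > start
  start <- pmax(start[keep], 0); end <- end[keep]
  if (!length(start)) return(tibble::tibble(start = numeric(), end = numeric()))
  # union of sorted half-open intervals
  merged_start <- start[1]; merged_end <- end[1]
  out_s <- numeric(); out_e <- numeric()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= merged_end) {
      merged_end <- max(merged_end, end[i])
    } else {
      out_s <- c(out_s, merged_start); out_e <- c(out_e, merged_end)
      merged_start <- start[i]; merged_end <- end[i]
    }
  }
  tibble::tibble(start = c(out_s, merged_start), end = c(out_e, merged_end))
}

#' Medication possession ratio over the follow-up window
#'
#' Total possession-covered days (union of per-dose coverage, truncated at the
#' window) divided by the number of days in the window.
#'
#' @inheritParams track_schedule
#' @return A fraction in `[0, 1]`.
#' @examples
#' compute_mpr(0, dosing_regimen("mepolizumab")) # 28/365
#' @export
compute_mpr <- function(dose_dates, regimen, config = engine_config()) {
  cov <- coverage_intervals(dose_dates, regimen, config)
  sum(cov$end - cov$start) / config$followup_days
}

#' Four-category adherence classification
#'
#' Applies the gap-and-dose-count rules for the patient's biologic over the
#' follow-up window. Treatment discontinuation takes precedence: a terminal
#' gap from the last dose to the end of follow-up at or above the phase's
#' discontinuation limit classifies the patient as `discontinuation`
#' regardless of the other rules. Otherwise the patient is `adherent` when
#' every inter-dose gap is within its phase window and the dose count
#' (including the index dose) meets the adherent minimum;
#' `minimally_adherent` when at least one prolonged gap co-occurs with a dose
#' count at or below the minimal maximum; and `partially_adherent` otherwise.
#' Gap thresholds are compared against raw inter-dose gaps; the windows
#' (twice the dosing interval) already embody one full missed cycle, so the
#' scheduling buffer is not added again.
#'
#' @param dose_dates Numeric day offsets (first dose at day 0), a list of
#'   such vectors, or a matrix with one equal-length sequence per row.
#' @inheritParams track_schedule
#' @return A character vector of categories (see `adherence_categories`).
#' @examples
#' classify_adherence(seq(0, by = 14, length.out = 26),
#'                    dosing_regimen("dupilumab"))
#' @export
classify_adherence <- function(dose_dates, regimen, config = engine_config()) {
  if (is.matrix(dose_dates)) {
    return(classify_matrix(dose_dates, regimen, config))
  }
  if (is.list(dose_dates)) {
    lens <- lengths(dose_dates)
    out <- character(length(dose_dates))
    for (k in unique(lens)) {
      idx <- which(lens == k)
      m <- matrix(unlist(dose_dates[idx], use.names = FALSE),
                  ncol = k, byrow = TRUE)
      out[idx] <- classify_matrix(m, regimen, config)
    }
    return(out)
  }
  dose_dates <- prepare_doses(dose_dates)
  if (!length(dose_dates)) abort("at least one dose (the index dose) required")
  classify_matrix(matrix(dose_dates, nrow = 1), regimen, config)
}

classify_matrix <- function(dates, regimen, config) {
  storage.mode(dates) <- "double"
  codes <- if (isTRUE(regimen$infer)) {
    classify_dates_infer_cpp(
      dates, regimen_rules(dosing_regimen("omalizumab", "q2w")),
      regimen_rules(dosing_regimen("omalizumab", "q4w")),
      config$followup_days, 21)
  } else {
    classify_dates_cpp(dates, regimen_rules(regimen), config$followup_days)
  }
  adherence_categories[codes]
}

#' Exhaustively classify dose sequences on a day grid
#'
#' Enumerates every dose sequence that starts at day 0 with all later doses
#' on a `grid_step`-day grid up to `max_day`, up to `max_doses` doses, and
#' classifies each with the same kernel as [classify_adherence()]. Used to
#' characterize the classification rules (e.g. the largest dose count a
#' category can contain).
#'
#' @param regimen A concrete (non-inferred) [dosing_regimen()].
#' @param max_doses Maximum sequence length.
#' @param grid_step Grid spacing in days.
#' @param max_day Last grid day available to a dose.
#' @param config An [engine_config()].
#' @return A tibble with `n_doses`, `category`, `count` (counts of sequences).
#' @export
enumerate_classify <- function(regimen, max_doses, grid_step = 7,
                               max_day = 364, config = engine_config()) {
  if (isTRUE(regimen$infer)) {
    abort("enumerate_classify needs a concrete regimen (resolve omalizumab first)")
  }
  counts <- enumerate_grid_cpp(as.integer(grid_step), as.integer(max_day),
                               as.integer(max_doses), regimen_rules(regimen),
                               config$followup_days)
  tidyr::expand_grid(n_doses = seq_len(max_doses),
                     category = adherence_categories) |>
    dplyr::mutate(count = as.vector(t(counts)))
}

#' Binary per-bin adherence series
#'
#' Splits the follow-up into `n_bins` bins of `bin_days` days and marks bin t
#' adherent (1) when the possession-covered fraction of the bin meets
#' `coverage_threshold`.
#'
#' @inheritParams track_schedule
#' @return An integer 0/1 vector of length `config$n_bins`.
#' @export
adherence_series <- function(dose_dates, regimen, config = engine_config()) {
  cov <- coverage_intervals(dose_dates, regimen, config)
  as.integer(covered_in_bins(cov, config) >=
               config$coverage_threshold * config$bin_days)
}

# covered days per bin from a set of half-open intervals
covered_in_bins <- function(cov, config) {
  bins_start <- (seq_len(config$n_bins) - 1) * config$bin_days
  bins_end <- bins_start + config$bin_days
  out <- numeric(config$n_bins)
  for (i in seq_len(nrow(cov))) {
    out <- out + pmax(0, pmin(cov$end[i], bins_end) -
                        pmax(cov$start[i], bins_start))
  }
  out
}

#' Per-patient adherence summary for a cohort
#'
#' Runs the full adherence engine over every cohort patient: extracts the
#' index-biologic doses inside the follow-up window (as day offsets from the
#' index date), resolves the regimen (inferring the omalizumab schedule where
#' needed), and computes dose count, MPR, the four-way category and the
#' binary adherence series.
#'
#' @param bundle A `claims_bundle`.
#' @param cohort A cohort tibble with `patient_id`, `index_date`,
#'   `index_biologic` (e.g. from [apply_eligibility()]).
#' @param config An [engine_config()].
#' @return A tibble with one row per patient: `patient_id`, `index_biologic`,
#'   `regimen`, `n_doses`, `mpr`, `category`, and list-columns `dose_days`,
#'   `series` (integer 0/1), `coverage` (interval tibbles).
#' @export
compute_adherence <- function(bundle, cohort, config = engine_config()) {
  doses <- bundle$dispensings |>
    dplyr::inner_join(cohort, by = "patient_id") |>
    dplyr::filter(.data$drug_code == .data$index_biologic) |>
    dplyr::mutate(day = as.numeric(.data$dispense_date - .data$index_date)) |>
    dplyr::filter(.data$day >= 0, .data$day < config$followup_days)
  dose_map <- split(doses$day, doses$patient_id)
  purrr::pmap(cohort[c("patient_id", "index_biologic")],
              function(patient_id, index_biologic) {
    days <- prepare_doses(dose_map[[patient_id]] %||% 0)
    reg <- resolve_regimen(dosing_regimen(index_biologic), days)
    cov <- coverage_intervals(days, reg, config)
    series <- as.integer(covered_in_bins(cov, config) >=
                           config$coverage_threshold * config$bin_days)
    category <- classify_matrix(matrix(days, nrow = 1), reg, config)
    sched <- track_schedule(days, reg, config)
    tibble::tibble(
      patient_id = patient_id, index_biologic = index_biologic,
      regimen = reg$label, n_doses = length(days),
      mpr = sum(cov$end - cov$start) / config$followup_days,
      category = category,
      dose_days = list(days), on_schedule = list(sched$on_schedule),
      series = list(series), coverage = list(cov))
  }) |>
    dplyr::bind_rows()
}

#' Stack the adherence series of a cohort into a matrix
#'
#' @param adherence Output of [compute_adherence()].
#' @return An N x T integer matrix with patient ids as row names.
#' @export
adherence_series_matrix <- function(adherence) {
  m <- do.call(rbind, adherence$series)
  rownames(m) <- adherence$patient_id
  m
}
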