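# Synthetic claims cohort generator. Emulates the statistical structure the
# analysis assumes: five biologics with their approved dosing schedules,
# seven adherence archetypes (mixture of logistic-quadratic dose-taking
# curves over follow-up bins), adherence-dependent exacerbation/HCRU event
# rates, and per-line pharmacy costs with a biologic flag. Everything is
# deterministic under a fixed seed.

#' Packaged adherence archetypes
#'
#' Seven trajectory shapes, from sustained high adherence through U-shaped
#' lapses, late and early stoppers, intermittent dosing, and near-immediate
#' discontinuation. Each archetype is a per-bin dose-taking probability curve
#' (13 four-week bins), parameterized as a logistic-quadratic function of
#' standardized bin time so the curves live in the same family the trajectory
#' model fits. Mixture weights and implied mean MPRs approximate the cluster
#' distribution reported for biologic users in Japanese claims.
#'
#' @param n_bins Number of follow-up bins.
#' @return A tibble: `name`, `weight`, `curve` (list of probability vectors).
#' @export
archetype_defaults <- function(n_bins = 13) {
  t_std <- seq(-1, 1, length.out = n_bins)
  curve <- function(a, b, c) plogis(a + b * t_std + c * t_std^2)
  out <- tibble::tribble(
    ~name,           ~weight, ~a,   ~b,    ~c,
    "highest",        0.3915,  3.9,   0.0,  0.0,
    "early_u",        0.0703,  1.8,  12.0, 12.0,
    "late_u",         0.1328,  0.5, -10.0, 13.0,
    "late_stop",      0.0897,  3.2,  -9.0,  0.0,
    "intermittent",   0.0612, -0.2,   0.0,  0.0,
    "delayed_stop",   0.1252, -2.2,  -9.0, -2.5,
    "lowest",         0.1292, -3.4,   0.0,  0.0
  )
  out$weight <- out$weight / sum(out$weight)
  out$curve <- purrr::pmap(out[c("a", "b", "c")], curve)
  out[c("name", "weight", "curve")]
}

#' Outcome-generating rates and cost parameters
#'
#' Baseline event rates are per patient-year during possession-covered
#' (adherent) time; during uncovered time the asthma-related rates are
#' multiplied by `rate_ratio`. Biologic dose costs are per-administration
#' list-price approximations in JPY; non-biologic pharmacy cost arises from a
#' background controller refill stream plus per-event medication lines.
#'
#' @param rate_ratio Multiplicative effect of an uncovered period on
#'   asthma-related event rates (> 1 for harm).
#' @param asthma_admission,asthma_ed,ocs_course,iv_course Asthma-related
#'   event rates (per patient-year, covered time).
#' @param other_admission,other_ed Non-asthma encounter rates (adherence
#'   independent).
#' @param biologic_dose_cost Named per-dose costs (JPY).
#' @param controller_cost,admission_rx_cost,ed_rx_cost,ocs_course_cost,iv_rx_cost
#'   Non-biologic pharmacy line costs (JPY).
#' @param frailty_sd SD of a patient-level log-normal frailty multiplying all
#'   asthma event rates (0 = plain Poisson).
#' @return An `outcome_rates` list.
#' @export
outcome_rates <- function(rate_ratio = 2.0,
                          asthma_admission = 0.06, asthma_ed = 0.08,
                          ocs_course = 0.5, iv_course = 0.05,
                          other_admission = 0.12, other_ed = 0.08,
                          biologic_dose_cost = c(
                            benralizumab = 357000, dupilumab = 66000,
                            mepolizumab = 160000, omalizumab = 69000,
                            tezepelumab = 190000),
                          controller_cost = 8000, admission_rx_cost = 25000,
                          ed_rx_cost = 8000, ocs_course_cost = 1500,
                          iv_rx_cost = 10000, frailty_sd = 0) {
  stopifnot(rate_ratio > 0, asthma_admission >= 0, asthma_ed >= 0,
            ocs_course >= 0, iv_course >= 0, other_admission >= 0,
            other_ed >= 0, all(biologic_dose_cost >= 0), frailty_sd >= 0)
  structure(as.list(environment()), class = "outcome_rates")
}

#' Generator configuration
#'
#' @param n_patients Cohort size.
#' @param biologic_mix Named biologic market-share proportions (normalized).
#' @param archetypes Archetype set ([archetype_defaults()]).
#' @param rates An [outcome_rates()] object.
#' @param switch_prob Probability a patient switches biologic during
#'   follow-up (default 0.128, the share observed among eligible biologic
#'   initiators in Japanese claims).
#' @param exclusion_probs Named probabilities of injecting an exclusion
#'   diagnosis (codes from `diagnosis_codes`); default none, so a generated
#'   cohort passes eligibility intact.
#' @param seed Integer seed; fixed seed implies byte-identical output.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_patients = 2500,
                             biologic_mix = c(
                               benralizumab = 0.3719, mepolizumab = 0.2882,
                               dupilumab = 0.1398, omalizumab = 0.1291,
                               tezepelumab = 0.0523),
                             archetypes = archetype_defaults(),
                             rates = outcome_rates(),
                             switch_prob = 0.128,
                             exclusion_probs = numeric(),
                             seed = NULL) {
  stopifnot(n_patients >= 0, all(biologic_mix >= 0),
            all(names(biologic_mix) %in% asthma_biologics),
            switch_prob >= 0, switch_prob <= 1,
            abs(sum(archetypes$weight) - 1) < 1e-8)
  biologic_mix <- biologic_mix / sum(biologic_mix)
  structure(list(n_patients = n_patients, biologic_mix = biologic_mix,
                 archetypes = archetypes, rates = rates,
                 switch_prob = switch_prob, exclusion_probs = exclusion_probs,
                 seed = seed),
            class = "generator_config")
}

# one dose-taking pass through a regimen schedule: one adherence coin per
# 28-day bin (shared by all doses scheduled in that bin), +/- 7-day uniform
# jitter on taken doses, schedule re-anchored at each taken dose
simulate_doses <- function(regimen, curve, followup = 365, bin_days = 28,
                           jitter = 7) {
  n_bins <- length(curve)
  bin_coins <- runif(n_bins) < curve
  taken <- 0
  n_taken <- 1L
  last <- 0
  slot <- interval_at(regimen, 1L)
  while (slot < followup) {
    bin <- min(floor(slot / bin_days) + 1L, n_bins)
    if (bin_coins[bin]) {
      actual <- slot + sample.int(2L * jitter + 1L, 1L) - jitter - 1L
      actual <- min(max(actual, last + 1), followup - 1)
      taken <- c(taken, actual)
      n_taken <- n_taken + 1L
      last <- actual
      slot <- actual + interval_at(regimen, n_taken)
    } else {
      slot <- slot + interval_at(regimen, n_taken)
    }
  }
  taken
}

# scheduled-slot log for the generative->analytic consistency checks
simulate_doses_log <- function(regimen, curve, followup = 365, bin_days = 28,
                               jitter = 7) {
  n_bins <- length(curve)
  bin_coins <- runif(n_bins) < curve
  slot_day <- numeric(); slot_bin <- integer(); slot_taken <- logical()
  taken <- 0
  n_taken <- 1L
  last <- 0
  slot <- interval_at(regimen, 1L)
  while (slot < followup) {
    bin <- min(floor(slot / bin_days) + 1L, n_bins)
    take <- bin_coins[bin]
    slot_day <- c(slot_day, slot); slot_bin <- c(slot_bin, bin)
    slot_taken <- c(slot_taken, take)
    if (take) {
      actual <- slot + sample.int(2L * jitter + 1L, 1L) - jitter - 1L
      actual <- min(max(actual, last + 1), followup - 1)
      taken <- c(taken, actual)
      n_taken <- n_taken + 1L
      last <- actual
      slot <- actual + interval_at(regimen, n_taken)
    } else {
      slot <- slot + interval_at(regimen, n_taken)
    }
  }
  list(taken = taken,
       log = tibble::tibble(slot_day = slot_day, bin = slot_bin,
                            taken = slot_taken))
}

# events from an inhomogeneous Poisson process: baseline rate over covered
# intervals, rate * ratio over uncovered ones (rates per patient-year)
sample_piecewise_events <- function(covered, followup, base, ratio, frailty) {
  if (base <= 0) return(numeric())
  bounds <- sort(unique(c(0, covered$start, covered$end, followup)))
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1]
  is_cov <- purrr::map_lgl(starts, function(s) {
    any(covered$start <= s & covered$end > s)
  })
  rate <- base * frailty * ifelse(is_cov, 1, ratio)
  counts <- rpois(length(starts), (ends - starts) / 365 * rate)
  unlist(purrr::pmap(list(starts, ends, counts), function(s, e, k) {
    # day 1 at the earliest: day 0 is the index dispensing day
    if (k == 0) numeric() else pmax(floor(runif(k, s, e)), 1)
  }))
}

month_key <- function(dates) {
  as.integer(format(dates, "%Y")) * 12L + as.integer(format(dates, "%m"))
}

#' Generate a synthetic claims cohort
#'
#' Draws each patient's biologic, adherence archetype and demographics,
#' simulates the dose-taking process (index dose at day 0, then one
#' adherence decision per four-week bin with +/- 7-day jitter and dynamic
#' re-anchoring), and layers adherence-dependent exacerbation, encounter,
#' diagnosis and pharmacy-cost records on top. Every patient has at least 30
#' days of enrollment before the index date and at least 365 after, an
#' asthma diagnosis before the index, and pre-index ICS and LABA
#' prescriptions, so a generated cohort passes eligibility unless exclusion
#' injections are switched on. With `switch_prob > 0` a random subset of
#' patients switches biologic mid-follow-up (via [inject_switchers()]).
#'
#' @param config A [generator_config()].
#' @return A validated `claims_bundle` with two attributes: `truth` (tibble
#'   with the generating archetype, biologic, omalizumab schedule and switch
#'   status per patient) and `dose_log` (per scheduled dose slot: day, bin,
#'   taken), used by the consistency tests.
#' @export
generate_cohort <- function(config = generator_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_patients
  empty_table <- function(name) {
    schema <- bundle_schemas[[name]]
    tbl <- tibble::as_tibble(purrr::map(schema, function(type) {
      vector(switch(type, Date = "double", type), 0)
    }))
    for (col in names(schema)[schema == "Date"]) {
      tbl[[col]] <- as.Date(tbl[[col]], origin = "1970-01-01")
    }
    tbl
  }
  if (n == 0) {
    bundle <- claims_bundle(empty_table("patients"), empty_table("dispensings"),
                            empty_table("diagnoses"), empty_table("encounters"))
    attr(bundle, "truth") <- tibble::tibble(
      patient_id = character(), biologic = character(),
      oma_schedule = character(), archetype = character(),
      switched = logical())
    return(bundle)
  }
  r <- config$rates
  arch <- config$archetypes
  econf <- engine_config()
  followup <- econf$followup_days

  ids <- sprintf("P%05d", seq_len(n))
  biologics <- sample(names(config$biologic_mix), n, replace = TRUE,
                      prob = config$biologic_mix)
  archetype <- sample(arch$name, n, replace = TRUE, prob = arch$weight)
  oma_schedule <- ifelse(biologics == "omalizumab",
                         sample(c("q2w", "q4w"), n, replace = TRUE),
                         NA_character_)
  index_date <- as.Date("2016-01-01") + sample.int(2556, n, replace = TRUE) - 1
  age <- pmin(pmax(round(rnorm(n, 66, 13)), 18), 95)
  sex <- sample(c("male", "female"), n, replace = TRUE, prob = c(0.388, 0.612))
  smoking <- sample(c("current_former", "never", "unknown"), n, replace = TRUE,
                    prob = c(0.137, 0.236, 0.627))
  frailty <- if (r$frailty_sd > 0) {
    exp(rnorm(n, -r$frailty_sd^2 / 2, r$frailty_sd))
  } else rep(1, n)

  pt_rows <- vector("list", n); disp_rows <- vector("list", n)
  dx_rows <- vector("list", n); enc_rows <- vector("list", n)
  log_rows <- vector("list", n)

  for (i in seq_len(n)) {
    id <- ids[i]
    regimen <- if (biologics[i] == "omalizumab") {
      dosing_regimen("omalizumab", oma_schedule[i])
    } else dosing_regimen(biologics[i])
    curve <- arch$curve[[match(archetype[i], arch$name)]]
    sim <- simulate_doses_log(regimen, curve, followup, econf$bin_days,
                              econf$buffer_days)
    doses <- sim$taken
    log_rows[[i]] <- dplyr::mutate(sim$log, patient_id = id,
                                   archetype = archetype[i],
                                   biologic = biologics[i])

    # pre-index history: asthma diagnosis, ICS + LABA in its 90-day window
    dx0 <- -sample(30:540, 1)
    combo <- runif(1) < 0.5
    ctrl_days <- dx0 - sample(0:80, if (combo) 1 else 2, replace = TRUE)
    dx_days <- dx0
    dx_codes <- "asthma"

    cov <- coverage_intervals(doses, regimen, econf)
    ev <- list(
      asthma_admission = sample_piecewise_events(
        cov, followup, r$asthma_admission, r$rate_ratio, frailty[i]),
      asthma_ed = sample_piecewise_events(
        cov, followup, r$asthma_ed, r$rate_ratio, frailty[i]),
      ocs_course = sample_piecewise_events(
        cov, followup, r$ocs_course, r$rate_ratio, frailty[i]),
      iv_course = sample_piecewise_events(
        cov, followup, r$iv_course, r$rate_ratio, frailty[i]),
      other_admission = sample_piecewise_events(
        cov, followup, r$other_admission, 1, 1),
      other_ed = sample_piecewise_events(cov, followup, r$other_ed, 1, 1))

    # encounters
    enc <- list()
    if (length(ev$asthma_admission)) {
      los <- 1 + rpois(length(ev$asthma_admission), 3)
      enc$aa <- tibble::tibble(start = ev$asthma_admission,
                               end = ev$asthma_admission + los - 1,
                               type = "inpatient_admission",
                               asthma = TRUE, planned = FALSE)
    }
    if (length(ev$asthma_ed)) {
      enc$ae <- tibble::tibble(start = ev$asthma_ed, end = ev$asthma_ed,
                               type = "ed_visit", asthma = TRUE,
                               planned = FALSE)
    }
    if (length(ev$other_admission)) {
      los <- 1 + rpois(length(ev$other_admission), 4)
      enc$oa <- tibble::tibble(start = ev$other_admission,
                               end = ev$other_admission + los - 1,
                               type = "inpatient_admission", asthma = FALSE,
                               planned = runif(length(los)) < 0.3)
    }
    if (length(ev$other_ed)) {
      enc$oe <- tibble::tibble(start = ev$other_ed, end = ev$other_ed,
                               type = "ed_visit", asthma = FALSE,
                               planned = FALSE)
    }
    enc <- dplyr::bind_rows(enc)

    # dispensings: biologic doses, controller refills, event-linked lines
    d <- list()
    d$bio <- tibble::tibble(
      day = doses, drug = biologics[i], ds = 0L, qty = 1,
      cost = r$biologic_dose_cost[[biologics[i]]], steroid = "none")
    d$pre <- tibble::tibble(
      day = ctrl_days, drug = if (combo) "ics_laba" else c("ics", "laba"),
      ds = 30L, qty = 1, cost = r$controller_cost / 2, steroid = "none")
    refill_days <- seq(30, 360, by = 30)
    refill_keep <- runif(length(refill_days)) < 0.9
    if (any(refill_keep)) {
      rd <- refill_days[refill_keep]
      d$ctrl <- tibble::tibble(day = rd, drug = "ics_laba", ds = 30L, qty = 1,
                               cost = r$controller_cost, steroid = "none")
      dx_visit <- runif(length(rd)) < 0.8
      dx_days <- c(dx_days, rd[dx_visit])
      dx_codes <- c(dx_codes, rep("asthma", sum(dx_visit)))
    }
    if (length(ev$ocs_course)) {
      ds <- sample(3:14, length(ev$ocs_course), replace = TRUE)
      d$ocs <- tibble::tibble(day = ev$ocs_course, drug = "ocs", ds = ds,
                              qty = ds * 30, cost = r$ocs_course_cost,
                              steroid = "prednisolone")
      dx_days <- c(dx_days, ev$ocs_course)
      dx_codes <- c(dx_codes, rep("asthma", length(ev$ocs_course)))
    }
    if (length(ev$iv_course)) {
      d$iv <- tibble::tibble(day = ev$iv_course, drug = "iv_steroid", ds = 1L,
                             qty = 125, cost = r$iv_rx_cost,
                             steroid = "methylprednisolone")
      dx_days <- c(dx_days, ev$iv_course)
      dx_codes <- c(dx_codes, rep("asthma", length(ev$iv_course)))
    }
    if (length(ev$asthma_admission)) {
      d$arx <- tibble::tibble(day = ev$asthma_admission, drug = "other",
                              ds = 1L, qty = 1, cost = r$admission_rx_cost,
                              steroid = "none")
      dx_days <- c(dx_days, ev$asthma_admission)
      dx_codes <- c(dx_codes, rep("asthma", length(ev$asthma_admission)))
    }
    if (length(ev$asthma_ed)) {
      d$erx <- tibble::tibble(day = ev$asthma_ed, drug = "other", ds = 1L,
                              qty = 1, cost = r$ed_rx_cost, steroid = "none")
      dx_days <- c(dx_days, ev$asthma_ed)
      dx_codes <- c(dx_codes, rep("asthma", length(ev$asthma_ed)))
    }
    d <- dplyr::bind_rows(d)

    # exclusion-condition injections
    for (code in names(config$exclusion_probs)) {
      if (runif(1) < config$exclusion_probs[[code]]) {
        dx_days <- c(dx_days, -sample(1:400, 1))
        dx_codes <- c(dx_codes, code)
      }
    }

    enroll_start <- min(c(dx_days, ctrl_days, -30)) - sample(10:90, 1)
    enroll_end <- followup + sample(10:180, 1)

    pt_rows[[i]] <- tibble::tibble(
      patient_id = id,
      birth_year = as.integer(format(index_date[i], "%Y")) - age[i],
      sex = sex[i],
      enrollment_start = index_date[i] + enroll_start,
      enrollment_end = index_date[i] + enroll_end,
      smoking_status = smoking[i])
    disp_rows[[i]] <- tibble::tibble(
      patient_id = id, drug_code = d$drug,
      dispense_date = index_date[i] + d$day,
      days_supplied = as.integer(d$ds), quantity = d$qty, cost = d$cost,
      is_biologic = d$drug %in% asthma_biologics, steroid_compound = d$steroid)
    dx_rows[[i]] <- tibble::tibble(
      patient_id = id, code = dx_codes,
      diagnosis_date = index_date[i] + dx_days)
    enc_rows[[i]] <- if (nrow(enc)) {
      tibble::tibble(
        patient_id = id, encounter_type = enc$type,
        start_date = index_date[i] + enc$start,
        end_date = index_date[i] + enc$end,
        asthma_related = enc$asthma, planned = enc$planned)
    }
  }

  enc_tbl <- dplyr::bind_rows(enc_rows)
  if (!nrow(enc_tbl)) enc_tbl <- empty_table("encounters")
  bundle <- claims_bundle(
    dplyr::bind_rows(pt_rows),
    dplyr::bind_rows(disp_rows),
    dplyr::bind_rows(dx_rows),
    enc_tbl)
  truth <- tibble::tibble(patient_id = ids, biologic = biologics,
                          oma_schedule = oma_schedule, archetype = archetype,
                          switched = FALSE)
  dose_log <- dplyr::bind_rows(log_rows)
  if (config$switch_prob > 0) {
    bundle <- inject_switchers(bundle, config$switch_prob, rates = r)
    truth$switched <- truth$patient_id %in% attr(bundle, "switched_ids")
  }
  attr(bundle, "truth") <- truth
  attr(bundle, "dose_log") <- dose_log
  bundle
}

#' Inject biologic switchers into a generated bundle
#'
#' Selects patients with probability `switch_prob`; each selected patient's
#' index-biologic dispensings after a random switch day are removed and
#' replaced by dispensings of a different biologic dosed from the switch day
#' onwards. The switch is recoverable by [detect_switch()].
#'
#' @param bundle A `claims_bundle` from [generate_cohort()].
#' @param switch_prob Probability in `[0, 1]`.
#' @param seed Optional seed (the generator calls this inside its own seeded
#'   stream).
#' @param rates An [outcome_rates()] (for the new biologic's dose cost).
#' @return The modified bundle, with attribute `switched_ids`.
#' @export
inject_switchers <- function(bundle, switch_prob, seed = NULL,
                             rates = outcome_rates()) {
  if (switch_prob < 0 || switch_prob > 1) {
    abort("switch_prob must be in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  if (switch_prob == 0) {
    attr(bundle, "switched_ids") <- character()
    return(bundle)
  }
  idx <- find_index(bundle$dispensings)
  pick <- idx$patient_id[runif(nrow(idx)) < switch_prob]
  disp <- bundle$dispensings
  new_rows <- vector("list", length(pick))
  for (j in seq_along(pick)) {
    id <- pick[j]
    row <- idx[idx$patient_id == id, ]
    switch_day <- sample(60:300, 1)
    switch_date <- row$index_date + switch_day
    drop <- disp$patient_id == id & disp$drug_code == row$index_biologic &
      disp$dispense_date > switch_date
    disp <- disp[!drop, ]
    new_bio <- sample(setdiff(asthma_biologics, row$index_biologic), 1)
    regimen <- if (new_bio == "omalizumab") {
      dosing_regimen("omalizumab", sample(c("q2w", "q4w"), 1))
    } else dosing_regimen(new_bio)
    day <- switch_day
    days <- day
    k <- 1L
    repeat {
      day <- day + interval_at(regimen, k)
      if (day >= 365) break
      if (runif(1) < 0.8) {
        actual <- min(day + sample(-7:7, 1), 364)
        days <- c(days, actual)
        k <- k + 1L
        day <- actual
      }
    }
    new_rows[[j]] <- tibble::tibble(
      patient_id = id, drug_code = new_bio,
      dispense_date = row$index_date + days,
      days_supplied = 0L, quantity = 1,
      cost = rates$biologic_dose_cost[[new_bio]],
      is_biologic = TRUE, steroid_compound = "none")
  }
  out <- claims_bundle(bundle$patients,
                       dplyr::bind_rows(disp, dplyr::bind_rows(new_rows)),
                       bundle$diagnoses, bundle$encounters)
  attr(out, "truth") <- attr(bundle, "truth")
  attr(out, "dose_log") <- attr(bundle, "dose_log")
  attr(out, "switched_ids") <- pick
  out
}
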