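# Adherence-outcome association machinery: person-period construction
# (covered = adherent vs uncovered = non-adherent time), random-intercept
# Poisson count models with a negative-binomial switch under overdispersion,
# linear mixed cost models, group comparison tests and standardized mean
# differences.

#' Build person-periods from coverage intervals
#'
#' Partitions each patient's follow-up into maximal possession-covered
#' (adherent) and uncovered (non-adherent) intervals, assigns dated events
#' and costs to the interval containing their day, and merges contiguous
#' same-state intervals. Person-days sum to the follow-up length for every
#' patient.
#'
#' @param adherence Output of [compute_adherence()] (needs the `coverage`
#'   list-column).
#' @param events Optional tibble `patient_id`, `event_type`, `day` (e.g.
#'   [detect_exacerbations()] output); one count column per type is added.
#' @param costs Optional tibble `patient_id`, `day`, `cost`; summed per
#'   period into a `cost` column.
#' @param followup_days Follow-up length (must match the engine config).
#' @return A tibble: `patient_id`, `state`
#'   (`"adherent"`/`"nonadherent"`), `start`, `end` (half-open), `days`,
#'   event-count columns, `cost`.
#' @export
build_person_periods <- function(adherence, events = NULL, costs = NULL,
                                 followup_days = 365) {
  periods <- purrr::map2(adherence$patient_id, adherence$coverage,
                         function(id, cov) {
    bounds <- sort(unique(c(0, cov$start, cov$end, followup_days)))
    bounds <- bounds[bounds >= 0 & bounds <= followup_days]
    start <- bounds[-length(bounds)]
    end <- bounds[-1]
    covered <- purrr::map_lgl(start, function(s) {
      any(cov$start <= s & cov$end > s)
    })
    # merge contiguous same-state intervals
    grp <- cumsum(c(TRUE, covered[-1] != covered[-length(covered)]))
    tibble::tibble(
      patient_id = id,
      state = ifelse(tapply(covered, grp, `[`, 1), "adherent", "nonadherent"),
      start = as.vector(tapply(start, grp, min)),
      end = as.vector(tapply(end, grp, max)))
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(state = factor(.data$state,
                                 levels = c("adherent", "nonadherent")),
                  days = .data$end - .data$start) |>
    dplyr::filter(.data$days > 0)
  if (!is.null(events) && nrow(events)) {
    bad <- events$day < 0 | events$day >= followup_days
    if (any(bad)) abort("event outside the follow-up window")
    for (type in unique(events$event_type)) {
      ev <- events[events$event_type == type, ]
      col <- paste0("n_", type)
      periods[[col]] <- purrr::pmap_int(
        periods[c("patient_id", "start", "end")],
        function(patient_id, start, end) {
          sum(ev$patient_id == patient_id & ev$day >= start & ev$day < end)
        })
    }
  }
  if (!is.null(costs) && nrow(costs)) {
    periods$cost <- purrr::pmap_dbl(
      periods[c("patient_id", "start", "end")],
      function(patient_id, start, end) {
        sum(costs$cost[costs$patient_id == patient_id &
                         costs$day >= start & costs$day < end])
      })
  }
  periods
}

new_association <- function(outcome, family, estimate, log_estimate, se,
                            p_value, dispersion = NA_real_, fit = NULL,
                            note = NA_character_) {
  structure(list(outcome = outcome, family = family, estimate = estimate,
                 log_estimate = log_estimate, se = se, p_value = p_value,
                 dispersion = dispersion, fit = fit, note = note),
            class = "adherence_association")
}

#' @export
print.adherence_association <- function(x, ...) {
  cat(sprintf("<adherence_association> %s [%s]\n", x$outcome, x$family))
  cat(sprintf("  estimate %.4f (se of log/raw effect %.4f), p = %.3g\n",
              x$estimate, x$se, x$p_value))
  if (!is.na(x$dispersion)) {
    cat(sprintf("  Pearson dispersion %.3f\n", x$dispersion))
  }
  invisible(x)
}

#' @rdname fit_count_glmm
#' @param x An `adherence_association`.
#' @param ... Unused.
#' @export
tidy.adherence_association <- function(x, ...) {
  tibble::tibble(outcome = x$outcome, family = x$family,
                 estimate = x$estimate, log_estimate = x$log_estimate,
                 se = x$se, p_value = x$p_value, dispersion = x$dispersion,
                 note = x$note)
}

#' Random-intercept Poisson count model on person-periods
#'
#' Fits `count ~ state + offset(log(days)) + (1 | patient)` with a Poisson
#' response by adaptive Gauss-Hermite maximum likelihood, and returns the
#' rate ratio of non-adherent versus adherent person-time
#' (`exp` of the state coefficient).
#'
#' @param periods Output of [build_person_periods()].
#' @param outcome Name of a period count column (e.g. `"n_ed_visit"`).
#' @param nagq Number of adaptive quadrature nodes (default 15; 1 = Laplace).
#' @return An `adherence_association` (family `"poisson_glmm"`); use
#'   `tidy()` for a one-row tibble. All-zero outcomes return a degenerate
#'   flagged result rather than an error.
#' @export
fit_count_glmm <- function(periods, outcome, nagq = 15) {
  y <- periods[[outcome]]
  if (is.null(y)) abort(sprintf("no column '%s' in periods", outcome))
  if (all(y == 0)) {
    return(new_association(outcome, "poisson_glmm", NA_real_, NA_real_,
                           NA_real_, NA_real_,
                           note = "degenerate: all counts zero"))
  }
  dat <- data.frame(y = y, state = periods$state,
                    days = periods$days, patient_id = periods$patient_id)
  fit <- lme4::glmer(y ~ state + offset(log(days)) + (1 | patient_id),
                     data = dat, family = poisson, nAGQ = nagq,
                     control = lme4::glmerControl(calc.derivs = FALSE))
  sm <- summary(fit)$coefficients
  est <- sm["statenonadherent", "Estimate"]
  se <- sm["statenonadherent", "Std. Error"]
  conv <- length(fit@optinfo$conv$lme4$messages) == 0
  new_association(outcome, "poisson_glmm", exp(est), est, se,
                  2 * pnorm(-abs(est / se)),
                  dispersion = pearson_dispersion(fit), fit = fit,
                  note = if (conv) NA_character_ else "convergence warning")
}

pearson_dispersion <- function(fit) {
  sum(residuals(fit, type = "pearson")^2) / df.residual(fit)
}

#' Overdispersion check and negative-binomial switch
#'
#' Computes the Pearson chi-square / df statistic of a fitted Poisson count
#' model; when it exceeds `threshold` the model is refit with a
#' negative-binomial (gamma-mixed) response.
#'
#' @param assoc An `adherence_association` from [fit_count_glmm()].
#' @param periods The person-period table the model was fit on.
#' @param threshold Dispersion statistic above which the switch is made
#'   (default 1.5).
#' @return A list: `dispersion`, `use_negbin`, and `assoc` (the original or
#'   the refitted negative-binomial association).
#' @export
dispersion_switch <- function(assoc, periods, threshold = 1.5) {
  disp <- assoc$dispersion
  if (is.na(disp) || disp <= threshold) {
    return(list(dispersion = disp, use_negbin = FALSE, assoc = assoc))
  }
  dat <- data.frame(y = periods[[assoc$outcome]], state = periods$state,
                    days = periods$days, patient_id = periods$patient_id)
  fit <- suppressMessages(lme4::glmer.nb(
    y ~ state + offset(log(days)) + (1 | patient_id), data = dat))
  sm <- summary(fit)$coefficients
  est <- sm["statenonadherent", "Estimate"]
  se <- sm["statenonadherent", "Std. Error"]
  out <- new_association(assoc$outcome, "negbin_glmm", exp(est), est, se,
                         2 * pnorm(-abs(est / se)),
                         dispersion = disp, fit = fit)
  list(dispersion = disp, use_negbin = TRUE, assoc = out)
}

#' Rate ratios for several outcomes, with the overdispersion switch applied
#'
#' @inheritParams fit_count_glmm
#' @inheritParams dispersion_switch
#' @param outcomes Count columns to model (default: all `n_*` columns).
#' @param adjust If `TRUE`, add a `p_adjusted` column with Benjamini-Hochberg
#'   adjusted p-values across the modeled outcomes. Off by default, matching
#'   the descriptive framing of this kind of analysis.
#' @return A tibble with one row per outcome (tidied associations).
#' @export
associate_counts <- function(periods, outcomes = NULL, nagq = 15,
                             threshold = 1.5, adjust = FALSE) {
  if (is.null(outcomes)) {
    outcomes <- grep("^n_", names(periods), value = TRUE)
  }
  out <- purrr::map(outcomes, function(o) {
    assoc <- fit_count_glmm(periods, o, nagq = nagq)
    if (!is.na(assoc$dispersion)) {
      assoc <- dispersion_switch(assoc, periods, threshold)$assoc
    }
    tidy(assoc)
  }) |>
    dplyr::bind_rows()
  if (adjust) {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  }
  out
}

#' Linear mixed model for period costs
#'
#' Fits `cost ~ state + (1 | patient)` by REML; the effect is the mean cost
#' difference of non-adherent versus adherent periods. A singular fit falls
#' back to the fixed-effects-only linear model with a warning.
#'
#' @param periods Person-periods with a `cost` column.
#' @return An `adherence_association` (family `"lmm"` or `"lm"`).
#' @export
fit_cost_lmm <- function(periods) {
  if (is.null(periods$cost)) abort("periods have no cost column")
  dat <- data.frame(cost = periods$cost, state = periods$state,
                    patient_id = periods$patient_id)
  scale_fac <- stats::sd(dat$cost)
  if (!is.finite(scale_fac) || scale_fac == 0) {
    # degenerate: no cost variation at all
    warn("costs are constant; zero effect with zero variance")
    return(new_association("cost", "lm", 0, NA_real_, 0, NA_real_,
                           note = "degenerate: constant costs"))
  }
  # fit on a unit-variance response so the optimizer's convergence checks are
  # scale-free; coefficients are mapped back to the cost scale afterwards
  dat$cost_std <- dat$cost / scale_fac
  fit <- suppressMessages(lme4::lmer(cost_std ~ state + (1 | patient_id),
                                     data = dat, REML = TRUE))
  if (lme4::isSingular(fit)) {
    warn("singular random-intercept fit; falling back to fixed effects only")
    lmfit <- stats::lm(cost ~ state, data = dat)
    sm <- summary(lmfit)$coefficients
    est <- sm["statenonadherent", "Estimate"]
    se <- sm["statenonadherent", "Std. Error"]
    return(new_association("cost", "lm", est, NA_real_, se,
                           sm["statenonadherent", "Pr(>|t|)"], fit = lmfit,
                           note = "singular LMM; OLS fallback"))
  }
  sm <- summary(fit)$coefficients
  est <- sm["statenonadherent", "Estimate"] * scale_fac
  se <- sm["statenonadherent", "Std. Error"] * scale_fac
  new_association("cost", "lmm", est, NA_real_, se,
                  2 * pnorm(-abs(est / se)), fit = fit)
}

#' Compare an outcome across adherence groups
#'
#' Continuous outcomes: residual normality is checked with a Shapiro-Wilk
#' test (on at most 5000 sampled residuals) and the comparison uses one-way
#' ANOVA when normality is not rejected at `normality_alpha`, otherwise
#' Kruskal-Wallis. Count outcomes: Poisson regression across groups,
#' switching to negative binomial when the Pearson dispersion exceeds
#' `dispersion_threshold`. Binary outcomes: logistic regression. Groups with
#' fewer than 2 observations are excluded with a warning.
#'
#' @param values Outcome vector.
#' @param groups Group labels, same length.
#' @param kind `"continuous"`, `"count"` or `"binary"`.
#' @param normality_alpha Shapiro-Wilk alpha for the ANOVA gate.
#' @param dispersion_threshold Pearson dispersion switch threshold.
#' @return A one-row tibble: `kind`, `method`, `statistic`, `df`, `p_value`.
#' @export
group_compare <- function(values, groups,
                          kind = c("continuous", "count", "binary"),
                          normality_alpha = 0.05,
                          dispersion_threshold = 1.5) {
  kind <- match.arg(kind)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.factor(as.character(groups[keep]))
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warn(sprintf("excluding group(s) with n < 2: %s",
                 paste(small, collapse = ", ")))
    keep <- !groups %in% small
    values <- values[keep]; groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2) abort("need at least 2 groups with n >= 2")
  if (kind == "continuous") {
    resid <- values - stats::ave(values, groups)
    samp <- if (length(resid) > 5000) sample(resid, 5000) else resid
    normal <- if (length(unique(samp)) < 3 || stats::sd(samp) == 0) FALSE
    else shapiro.test(samp)$p.value >= normality_alpha
    if (normal) {
      fit <- summary(aov(values ~ groups))[[1]]
      return(tibble::tibble(kind = kind, method = "anova",
                            statistic = fit$`F value`[1],
                            df = fit$Df[1], p_value = fit$`Pr(>F)`[1]))
    }
    kw <- kruskal.test(values, groups)
    return(tibble::tibble(kind = kind, method = "kruskal_wallis",
                          statistic = unname(kw$statistic),
                          df = unname(kw$parameter), p_value = kw$p.value))
  }
  if (kind == "count") {
    fit <- glm(values ~ groups, family = poisson)
    disp <- sum(residuals(fit, "pearson")^2) / df.residual(fit)
    method <- "poisson_regression"
    if (disp > dispersion_threshold) {
      fit <- suppressWarnings(MASS::glm.nb(values ~ groups))
      method <- "negbin_regression"
    }
    an <- suppressWarnings(anova(fit, test = "Chisq"))
    return(tibble::tibble(kind = kind, method = method,
                          statistic = an$Deviance[2], df = an$Df[2],
                          p_value = an$`Pr(>Chi)`[2]))
  }
  fit <- glm(values ~ groups, family = binomial)
  an <- anova(fit, test = "Chisq")
  tibble::tibble(kind = kind, method = "logistic_regression",
                 statistic = an$Deviance[2], df = an$Df[2],
                 p_value = an$`Pr(>Chi)`[2])
}

#' Standardized mean differences across groups
#'
#' Continuous variables: pairwise \eqn{|\bar{x}_1 - \bar{x}_2| /
#' \sqrt{(s_1^2 + s_2^2)/2}}. Categorical variables: the multinomial
#' Mahalanobis formulation over the level proportions. The multi-group
#' summary is the maximum pairwise SMD. A zero pooled SD with unequal means
#' yields `Inf`.
#'
#' @param values A numeric vector (continuous) or factor/character
#'   (categorical).
#' @param groups Group labels, same length.
#' @return A tibble of pairwise SMDs (`group1`, `group2`, `smd`) with the
#'   multi-group maximum in attribute `"max_smd"` (also returned by
#'   `max(result$smd)`).
#' @export
compute_smd <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2) abort("need at least 2 groups")
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  rows <- purrr::map(pairs, function(pr) {
    v1 <- values[groups == pr[1]]; v2 <- values[groups == pr[2]]
    smd <- if (is.numeric(values)) {
      pooled <- sqrt((stats::var(v1) + stats::var(v2)) / 2)
      diffm <- abs(mean(v1) - mean(v2))
      if (pooled == 0) {
        if (diffm == 0) 0 else Inf
      } else diffm / pooled
    } else {
      cats <- sort(unique(as.character(values)))
      p1 <- as.vector(prop.table(table(factor(v1, cats))))
      p2 <- as.vector(prop.table(table(factor(v2, cats))))
      # drop one level; Mahalanobis distance of the proportion vectors
      d <- (p1 - p2)[-1]
      pbar <- ((p1 + p2) / 2)[-1]
      S <- diag(pbar, nrow = length(pbar)) - tcrossprod(pbar)
      sol <- tryCatch(solve(S, d), error = function(e) NULL)
      if (is.null(sol)) {
        if (all(abs(d) < 1e-12)) 0 else Inf
      } else sqrt(max(sum(d * sol), 0))
    }
    tibble::tibble(group1 = pr[1], group2 = pr[2], smd = smd)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "max_smd") <- max(out$smd)
  out
}

#' Simulate person-period count data with a known rate ratio
#'
#' A direct period-level simulator for model recovery and calibration
#' studies: each patient gets one covered and one uncovered period whose
#' lengths partition the follow-up, an optional log-normal frailty shared by
#' both periods, and Poisson event counts at `base_rate` (per patient-year)
#' during covered time and `base_rate * rate_ratio` during uncovered time.
#'
#' @param n_patients Number of patients.
#' @param rate_ratio True conditional rate ratio (1 = null).
#' @param base_rate Events per patient-year of covered time.
#' @param frailty_sd SD of the patient log-frailty.
#' @param followup_days Follow-up length.
#' @return A person-period tibble with an `n_event` column.
#' @export
simulate_period_counts <- function(n_patients, rate_ratio, base_rate = 2,
                                   frailty_sd = 0, followup_days = 365) {
  covered <- round(runif(n_patients, 0.25, 0.9) * followup_days)
  frailty <- if (frailty_sd > 0) {
    exp(rnorm(n_patients, -frailty_sd^2 / 2, frailty_sd))
  } else rep(1, n_patients)
  ids <- sprintf("S%05d", seq_len(n_patients))
  out <- tibble::tibble(
    patient_id = rep(ids, each = 2),
    state = factor(rep(c("adherent", "nonadherent"), times = n_patients),
                   levels = c("adherent", "nonadherent")),
    days = as.vector(rbind(covered, followup_days - covered)))
  rate <- rep(frailty, each = 2) * base_rate *
    rep(c(1, rate_ratio), times = n_patients)
  out$n_event <- rpois(nrow(out), rate * out$days / 365)
  out
}
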