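test_that("person-periods partition the follow-up exactly", {
  b <- generate_cohort(generator_config(n_patients = 120, seed = 31))
  res <- apply_eligibility(b)
  adh <- compute_adherence(b, res$cohort)
  events <- detect_exacerbations(b, res$cohort)
  periods <- build_person_periods(adh, events)
  days <- tapply(periods$days, periods$patient_id, sum)
  expect_true(all(days == 365))
  # contiguous same-state intervals were merged
  runs <- periods |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(ok = all(diff(as.integer(.data$state)) != 0))
  expect_true(all(runs$ok))
  # every event lands in a period containing its day
  expect_equal(sum(periods$n_ed_visit),
               sum(events$event_type == "ed_visit"))
})

test_that("a fully covered patient has a single adherent period", {
  adh <- tibble::tibble(
    patient_id = "P1",
    coverage = list(tibble::tibble(start = 0, end = 365)))
  p <- build_person_periods(adh)
  expect_equal(nrow(p), 1)
  expect_equal(as.character(p$state), "adherent")
  expect_equal(p$days, 365)
})

test_that("events after coverage ends fall in the non-adherent period", {
  adh <- tibble::tibble(
    patient_id = "P1",
    coverage = list(tibble::tibble(start = 0, end = 100)))
  ev <- tibble::tibble(patient_id = "P1", event_type = "ed_visit", day = 150)
  p <- build_person_periods(adh, ev)
  expect_equal(p$n_ed_visit[p$state == "nonadherent"], 1L)
  expect_equal(p$n_ed_visit[p$state == "adherent"], 0L)
  expect_error(
    build_person_periods(adh, dplyr::mutate(ev, day = 400)),
    "outside the follow-up")
})

test_that("the Poisson GLMM recovers a known rate ratio", {
  set.seed(32)
  periods <- simulate_period_counts(800, rate_ratio = 2, base_rate = 2,
                                    frailty_sd = 0.4)
  fit <- fit_count_glmm(periods, "n_event", nagq = 7)
  expect_equal(fit$family, "poisson_glmm")
  expect_lt(abs(fit$log_estimate - log(2)), 0.15 * log(2))
  expect_lt(fit$p_value, 1e-6)
})

test_that("with no patient heterogeneity the GLMM matches plain Poisson", {
  set.seed(33)
  periods <- simulate_period_counts(400, rate_ratio = 1.8, base_rate = 10,
                                    frailty_sd = 0)
  fit <- fit_count_glmm(periods, "n_event", nagq = 7)
  ref <- glm(n_event ~ state + offset(log(days)), data = periods,
             family = poisson)
  expect_equal(fit$log_estimate, unname(coef(ref)["statenonadherent"]),
               tolerance = 1e-3)
})

test_that("all-zero outcomes yield a flagged degenerate result", {
  periods <- simulate_period_counts(20, 1)
  periods$n_zero <- 0L
  fit <- fit_count_glmm(periods, "n_zero")
  expect_true(grepl("degenerate", fit$note))
  expect_true(is.na(fit$estimate))
})

test_that("the dispersion statistic calibrates and triggers the NB switch", {
  set.seed(34)
  stats <- replicate(20, {
    periods <- simulate_period_counts(150, rate_ratio = 2, base_rate = 3)
    fit_count_glmm(periods, "n_event", nagq = 1)$dispersion
  })
  expect_gt(mean(stats), 0.8)
  expect_lt(mean(stats), 1.2)

  # gamma-heterogeneous counts overdisperse and trigger the refit
  set.seed(35)
  periods <- simulate_period_counts(250, rate_ratio = 2, base_rate = 3)
  periods$n_event <- rpois(nrow(periods),
                           periods$n_event + rgamma(nrow(periods), 1, 0.5))
  fit <- fit_count_glmm(periods, "n_event", nagq = 1)
  sw <- dispersion_switch(fit, periods)
  expect_true(sw$use_negbin)
  expect_equal(sw$assoc$family, "negbin_glmm")

  # an infinite threshold never switches
  sw_inf <- dispersion_switch(fit, periods, threshold = Inf)
  expect_false(sw_inf$use_negbin)
  expect_equal(sw_inf$assoc$family, "poisson_glmm")
})

test_that("the cost LMM recovers a known state effect", {
  set.seed(36)
  n <- 600
  u <- rnorm(n, 0, 300)
  periods <- tibble::tibble(
    patient_id = rep(sprintf("C%04d", 1:n), each = 2),
    state = factor(rep(c("adherent", "nonadherent"), n),
                   levels = c("adherent", "nonadherent")),
    days = 180,
    cost = 2000 + rep(u, each = 2) +
      ifelse(rep(c(FALSE, TRUE), n), 500, 0) + rnorm(2 * n, 0, 400))
  fit <- fit_cost_lmm(periods)
  expect_equal(fit$family, "lmm")
  expect_lt(abs(fit$estimate - 500), 2 * fit$se)

  # identical costs: zero effect, zero variance, flagged
  flat <- dplyr::mutate(periods, cost = 1000)
  expect_warning(fit0 <- fit_cost_lmm(flat), "constant")
  expect_equal(fit0$estimate, 0)
  expect_true(grepl("degenerate", fit0$note))

  # no random-intercept variance: matches ordinary least squares
  set.seed(37)
  nouni <- dplyr::mutate(periods, cost = 2000 +
                           ifelse(state == "nonadherent", 500, 0) +
                           rnorm(2 * n, 0, 400))
  fit2 <- suppressWarnings(fit_cost_lmm(nouni))
  ols <- stats::lm(cost ~ state, data = nouni)
  expect_equal(fit2$estimate, unname(coef(ols)["statenonadherent"]),
               tolerance = 1e-4)
})

test_that("group comparisons pick the documented test branches", {
  set.seed(38)
  # identical groups: no evidence of difference
  v <- rep(rnorm(50), 2)
  g <- rep(c("a", "b"), each = 50)
  res <- group_compare(v, g, "continuous")
  expect_gt(res$p_value, 0.9)

  # strongly shifted normal groups: ANOVA branch, decisive
  v <- c(rnorm(50, 0, 1), rnorm(50, 2, 1))
  res <- group_compare(v, g, "continuous")
  expect_equal(res$method, "anova")
  expect_lt(res$p_value, 1e-3)

  # heavy tails fail the normality gate: Kruskal-Wallis branch
  v <- c(rcauchy(60), rcauchy(60, 3))
  res <- group_compare(v, rep(c("a", "b"), each = 60), "continuous")
  expect_equal(res$method, "kruskal_wallis")

  # counts: Poisson, switching to negative binomial under overdispersion
  v <- rpois(120, 3)
  res <- group_compare(v, rep(c("a", "b"), each = 60), "count")
  expect_equal(res$method, "poisson_regression")
  v <- rnbinom(120, mu = 3, size = 0.7)
  res <- group_compare(v, rep(c("a", "b"), each = 60), "count")
  expect_equal(res$method, "negbin_regression")

  # binary: logistic regression
  v <- rbinom(120, 1, rep(c(0.2, 0.6), each = 60))
  res <- group_compare(v, rep(c("a", "b"), each = 60), "binary")
  expect_equal(res$method, "logistic_regression")
  expect_lt(res$p_value, 0.01)

  # undersized groups are excluded with a warning
  expect_warning(
    group_compare(c(rnorm(30), 1), c(rep(c("a", "b"), each = 15), "c"),
                  "continuous"),
    "excluding")
})

test_that("standardized mean differences match their closed forms", {
  expect_equal(max(compute_smd(rep(c(1, 2, 3), 2),
                               rep(c("a", "b"), each = 3))$smd), 0)
  # means 0 and 1, both SD 1
  res <- compute_smd(c(-1, 0, 1, 0, 1, 2), rep(c("a", "b"), each = 3))
  expect_equal(res$smd, 1)
  # equal proportions: zero SMD for a binary covariate
  v <- rep(c("x", "y"), 10)
  res <- compute_smd(v, rep(c("a", "b"), each = 10))
  expect_equal(res$smd, 0)
  # known binary case: p1 = 0.5, p2 = 0.9
  v <- c(rep(c("x", "y"), each = 10), rep("x", 18), rep("y", 2))
  g <- rep(c("a", "b"), each = 20)
  p1 <- 0.5; p2 <- 0.9; pbar <- 0.7
  expect_equal(compute_smd(v, g)$smd,
               abs(p1 - p2) / sqrt(pbar * (1 - pbar)))
  # multi-group summary is the maximum pairwise SMD
  v <- c(rnorm(40, 0), rnorm(40, 0.3), rnorm(40, 2))
  g <- rep(c("a", "b", "c"), each = 40)
  res <- compute_smd(v, g)
  expect_equal(attr(res, "max_smd"), max(res$smd))
  expect_equal(nrow(res), 3)
})

test_that("associate_counts tidies one row per outcome", {
  set.seed(39)
  periods <- simulate_period_counts(150, rate_ratio = 2, base_rate = 2)
  periods$n_other <- rpois(nrow(periods), 0.2)
  out <- associate_counts(periods, nagq = 1)
  expect_equal(sort(out$outcome), c("n_event", "n_other"))
  expect_true(all(out$estimate[out$outcome == "n_event"] > 1))
})
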