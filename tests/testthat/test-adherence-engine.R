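test_that("omalizumab schedule inference follows the median-gap rule", {
  expect_equal(infer_omalizumab_regimen(c(0, 14, 28, 42)), "q2w")
  expect_equal(infer_omalizumab_regimen(c(0, 28, 56)), "q4w")
  # gaps {14, 14, 28, 28, 28} -> median 28 -> Q4W
  expect_equal(infer_omalizumab_regimen(c(0, 14, 28, 56, 84, 112)), "q4w")
  expect_equal(infer_omalizumab_regimen(0), "q4w")
  expect_error(infer_omalizumab_regimen(numeric()), "zero doses")
})

test_that("schedule tracking resets dynamically and applies the buffer", {
  dupi <- dosing_regimen("dupilumab")
  ts <- track_schedule(c(0, 14, 28), dupi)
  expect_true(all(ts$on_schedule))

  ts <- track_schedule(c(0, 22), dupi)
  expect_false(ts$on_schedule[2]) # |22 - 14| = 8 > 7
  # the schedule re-anchors at the actual date: next expected dose is day 36
  expect_equal(ts$date[2] + 14, 36)

  benra <- dosing_regimen("benralizumab")
  ts <- track_schedule(c(0, 28, 56, 112), benra)
  expect_true(all(ts$on_schedule))
  expect_equal(ts$expected, c(0, 28, 56, 112))

  # perturbing a perfect schedule by at most the buffer keeps every dose on
  # schedule, for every biologic
  set.seed(42)
  for (biologic in asthma_biologics) {
    reg <- dosing_regimen(biologic, omalizumab_schedule = "q4w")
    perfect <- 0
    while (tail(perfect, 1) < 300) {
      perfect <- c(perfect,
                   tail(perfect, 1) + interval_at(reg, length(perfect)))
    }
    for (rep in 1:20) {
      jitter <- c(0, sample(-7:7, length(perfect) - 1, replace = TRUE))
      # cumulative: each dose within 7 days of previous actual + interval
      dates <- perfect
      for (i in 2:length(dates)) {
        dates[i] <- dates[i - 1] + interval_at(reg, i - 1) + jitter[i]
      }
      expect_true(all(track_schedule(dates, reg)$on_schedule))
    }
  }
})

test_that("duplicate dose dates collapse with a warning", {
  expect_warning(out <- track_schedule(c(0, 14, 14, 28),
                                       dosing_regimen("dupilumab")),
                 "duplicate")
  expect_equal(nrow(out), 3)
})

test_that("MPR is the covered fraction of the follow-up window", {
  mepo <- dosing_regimen("mepolizumab")
  # 13 x 28 = 364 covered of 365 follow-up days; a perfect dupilumab
  # schedule covers the whole window exactly
  expect_equal(compute_mpr(seq(0, by = 28, length.out = 13), mepo), 364 / 365)
  expect_equal(compute_mpr(seq(0, by = 14, length.out = 27),
                           dosing_regimen("dupilumab")), 1)
  expect_equal(compute_mpr(0, mepo), 28 / 365)
  # overlapping coverage is unioned, not double counted
  expect_equal(compute_mpr(c(0, 10), mepo), 38 / 365)
})

test_that("MPR is monotone in doses and bounded", {
  set.seed(1)
  for (rep in 1:50) {
    biologic <- sample(asthma_biologics, 1)
    reg <- dosing_regimen(biologic)
    days <- sort(sample(0:364, sample(1:20, 1)))
    mpr <- compute_mpr(days, reg)
    expect_gte(mpr, 0); expect_lte(mpr, 1)
    extra <- sample(setdiff(0:364, days), 1)
    expect_gte(compute_mpr(sort(c(days, extra)), reg), mpr)
  }
})

test_that("the four-category classifier reproduces the worked rules", {
  dupi <- dosing_regimen("dupilumab")
  expect_equal(classify_adherence(seq(0, by = 14, length.out = 26), dupi),
               "adherent")
  # a single prolonged gap with a full dose count is partial adherence
  mepo <- dosing_regimen("mepolizumab")
  days <- cumsum(c(0, rep(28, 8), 60, rep(28, 3)))
  days <- days[days < 365]
  expect_equal(classify_adherence(days, mepo), "partially_adherent")
  # benralizumab stopping after the three Q4W doses is discontinuation
  benra <- dosing_regimen("benralizumab")
  expect_equal(classify_adherence(c(0, 28, 56), benra), "discontinuation")
})

test_that("exactly one category applies and categories partition a cohort", {
  set.seed(2)
  for (rep in 1:200) {
    biologic <- sample(asthma_biologics, 1)
    days <- sort(unique(c(0, sample(1:364, sample(0:15, 1)))))
    cat <- classify_adherence(days, dosing_regimen(biologic))
    expect_length(cat, 1)
    expect_true(cat %in% adherence_categories)
  }
  b <- generate_cohort(generator_config(n_patients = 150, seed = 3))
  res <- apply_eligibility(b)
  adh <- compute_adherence(b, res$cohort)
  expect_equal(sum(table(adh$category)), nrow(res$cohort))
})

test_that("classifier agrees with the brute-force oracle on random sequences", {
  set.seed(4)
  for (biologic in asthma_biologics) {
    reg <- dosing_regimen(biologic)
    seqs <- purrr::map(1:400, function(i) {
      n_extra <- sample(0:26, 1)
      sort(unique(c(0, sample(1:364, n_extra))))
    })
    engine <- classify_adherence(seqs, reg)
    oracle <- purrr::map_chr(seqs, oracle_classify, biologic = biologic)
    expect_identical(engine, oracle)
  }
})

test_that("the binary series reflects bin coverage and its threshold", {
  mepo <- dosing_regimen("mepolizumab")
  expect_equal(adherence_series(seq(0, by = 28, length.out = 13), mepo),
               rep(1L, 13))
  expect_equal(adherence_series(0, mepo), c(1L, rep(0L, 12)))
  # strict full-coverage rule zeroes a bin whose coverage ends mid-bin
  strict <- engine_config(coverage_threshold = 1)
  majority <- engine_config(coverage_threshold = 0.5)
  days <- c(0, 28, 56, 63) # coverage ends day 91: bin 4 (84..112) partial
  expect_equal(adherence_series(days, mepo, strict)[4], 0L)
  expect_equal(adherence_series(days, mepo, majority)[4], 0L)
  days <- c(0, 28, 56, 84) # covers through day 112: bin 4 fully
  expect_equal(adherence_series(days, mepo, strict)[4], 1L)
})

test_that("enumerate_classify matches per-sequence classification", {
  # spot-check the grid enumerator against direct calls on all 3-dose
  # benralizumab sequences
  benra <- dosing_regimen("benralizumab")
  grid <- seq(7, 364, by = 7)
  combos <- grid_combos(length(grid), 2)
  dates <- cbind(0, matrix(grid[combos], ncol = 2))
  direct <- classify_adherence(dates, benra)
  enum <- enumerate_classify(benra, max_doses = 3)
  enum3 <- enum[enum$n_doses == 3, ]
  expect_equal(enum3$count[match(adherence_categories, enum3$category)],
               as.vector(table(factor(direct, adherence_categories))))
})
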