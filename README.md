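# adheretraj

Dosing-schedule-aware adherence measurement, trajectory clustering, and
outcome analysis for biologic therapies in longitudinal claims data.

Biologics for severe asthma — benralizumab, dupilumab, mepolizumab,
omalizumab, tezepelumab — are injectables dispensed every 2, 4 or 8 weeks
rather than daily. Measuring adherence from pharmacy claims therefore needs
the approved dosing schedule of each product: a 30-day gap is routine for an
8-weekly product and a double miss for a 2-weekly one. `adheretraj` is aimed
at pharmacoepidemiologists and outcomes researchers working with such data.
It implements:

* a **dosing-schedule state machine** with a dynamic ±7-day buffer: the
  expected date of dose *k+1* is the actual date of dose *k* plus that
  phase's interval, so the schedule resets at every taken dose
  (benralizumab's Q4W→Q8W phase change and omalizumab's claims-inferred
  Q2W/Q4W schedule included);
* the **medication possession ratio** over a 12-month follow-up,
  MPR = covered days / 365, where each dose confers possession for its
  scheduled interval and overlaps are unioned;
* a **four-category rule engine** per product — adherent / partially
  adherent / minimally adherent / treatment discontinuation — from
  phase-specific gap windows, minimum dose counts, and terminal-gap
  discontinuation limits, with discontinuation taking precedence;
* **group-based trajectory modeling** of binary per-4-week adherence
  series: a K-component mixture of quadratic-logit Bernoulli trajectories,

  L = Π_i Σ_k π_k Π_t p_kt^y_it (1 − p_kt)^(1 − y_it),
  p_kt = logit⁻¹(β_k0 + β_k1 t + β_k2 t²),

  fit by EM with k-means-seeded restarts, BIC selection over K, and A–G
  labeling by descending class-mean MPR;
* **claims outcome phenotypes**: exacerbations (asthma admissions, asthma
  ED visits, and oral/IV corticosteroid courses near an asthma diagnosis
  month), all-cause and asthma-related HCRU, pharmacy costs including and
  excluding biologic lines, and corticosteroid exposure in prednisone
  equivalents;
* **association models** on covered vs uncovered person-time:
  random-intercept Poisson count models with a negative-binomial switch
  under overdispersion, linear mixed cost models, ANOVA/Kruskal–Wallis and
  logistic comparisons, and standardized mean differences;
* a **synthetic claims cohort generator** (seven adherence archetypes,
  adherence-dependent event rates, realistic per-product dose costs) so the
  entire pipeline can be exercised and tested without access to any
  proprietary claims database.

## Worked example

```r
library(adheretraj)
library(dplyr)

bundle <- generate_cohort(generator_config(n_patients = 500, seed = 2024))
res <- apply_eligibility(bundle)
adh <- compute_adherence(bundle, res$cohort)

count(adh, category) |> mutate(pct = round(100 * n / sum(n), 1))
#>   category               n   pct
#> 1 adherent             184  36.8
#> 2 discontinuation      203  40.6
#> 3 minimally_adherent    19   3.8
#> 4 partially_adherent    94  18.8

mean(adh$mpr)   # 0.607 — mean MPR 60.7%
```

All 500 generated patients satisfy the eligibility cascade (the attrition
table in `res$attrition` shows every criterion), and about 13% switch
biologic during follow-up. The four categories partition the cohort; the
mean MPR of about 61% reflects the packaged mixture of adherence
archetypes, from sustained high adherence down to immediate stoppers.

Trajectory clustering on the non-switchers:

```r
gbtm_set <- adh |> semi_join(filter(res$cohort, !switched), by = "patient_id")
fit <- fit_gbtm(adherence_series_matrix(gbtm_set), 7, gbtm_config(seed = 1))
lab <- label_clusters(fit, gbtm_set$mpr)
cluster_profile(lab, gbtm_set$mpr)
#>   label     n share_pct mean_mpr_pct
#> 1 A       168     38.3         91.9
#> 2 B        17      3.87        70.8
#> 3 C        56     12.8         67.9
#> 4 D        55     12.5         67.7
#> 5 E        52     11.8         37.9
#> 6 F        44     10.0         32.9
#> 7 G        47     10.7          8.21
```

Clusters are labeled A–G from highest to lowest mean MPR: here the largest
cluster (38% of patients) keeps possession ~92% of the year while the
lowest cluster retains only the induction doses (~8%). `autoplot(lab)`
draws the fitted trajectory curves; `select_k()` returns the full K-vs-BIC
table.

Outcomes stratified by adherence category:

```r
out <- build_outcome_table(bundle, res$cohort)
stratify_outcomes(out, adh$category,
                  outcomes = c("exac_total", "allcause_cost_incl"))
#>   group              outcome            n      mean pct_diff_vs_ref
#> 1 adherent           allcause_cost_incl 184 2.33e+6            0
#> 2 discontinuation    allcause_cost_incl 203 1.19e+6          -49.2
#> 3 minimally_adherent allcause_cost_incl  19 8.06e+5          -65.5
#> 4 partially_adherent allcause_cost_incl  94 1.71e+6          -26.7
#> 5 adherent           exac_total         184 0.832            0
#> 6 discontinuation    exac_total         203 1.05            26.8
#> 7 minimally_adherent exac_total          19 1.84           122.
#> 8 partially_adherent exac_total          94 1.06            27.9
```

Adherent patients have the fewest exacerbations (0.83 per patient-year vs
1.05–1.84 in less adherent groups, i.e. 27–122% relative increases) but the
highest all-cause pharmacy costs — ¥2.33M on average — because biologic
dispensings dominate; excluding biologic lines reverses the cost ordering.

Association of events with covered vs uncovered person-time:

```r
events <- detect_exacerbations(bundle, res$cohort)
periods <- build_person_periods(adh, events)
associate_counts(periods, outcomes = "n_ocs_iv_course", nagq = 7)
#>   outcome         family       estimate log_estimate    se p_value dispersion
#> 1 n_ocs_iv_course poisson_glmm     1.34        0.292 0.101 0.00398      0.826
```

Corticosteroid-course exacerbations occur 1.34 times as often per
person-day during uncovered time (p = 0.004); no overdispersion is
detected, so the Poisson family is kept. The estimate is attenuated
relative to the generator's within-patient rate ratio of 2.0 mainly by
biologic switchers, whose post-switch person-time counts as uncovered for
the index product even though they are on treatment — the same dilution a
real index-drug analysis faces.

## Package layout

| Module | Functions |
| --- | --- |
| Claims data model & IO | `claims_bundle()`, `read_bundle()`, `write_bundle()`, `validate_bundle()` |
| Synthetic cohort | `generator_config()`, `generate_cohort()`, `inject_switchers()`, `archetype_defaults()`, `outcome_rates()` |
| Cohort selection | `find_index()`, `apply_eligibility()`, `detect_switch()` |
| Adherence engine | `dosing_regimen()`, `track_schedule()`, `compute_mpr()`, `classify_adherence()`, `adherence_series()`, `compute_adherence()` |
| Trajectory model | `fit_gbtm()`, `select_k()`, `label_clusters()`, `cluster_profile()` |
| Outcomes & costs | `detect_exacerbations()`, `summarize_hcru()`, `summarize_costs()`, `steroid_exposure()`, `build_outcome_table()`, `stratify_outcomes()` |
| Association models | `build_person_periods()`, `fit_count_glmm()`, `dispersion_switch()`, `fit_cost_lmm()`, `group_compare()`, `compute_smd()` |

The methods vignette (`vignettes/adherence-methods.Rmd`) documents the
model assumptions, default choices, what the synthetic cohort does and does
not emulate, and known limitations.
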