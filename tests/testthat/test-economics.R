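test_that("cohort projection reproduces the published 1,000-patient groups", {
  # internal fused-only row: 200 of 433 called positive, 166 true positives
  tab <- table_from_confusion(166, 31, 34, 202)
  ev <- evaluate_strategy(tab, cutoff_set(0.5, 0.2, 0.5), "t1_t2_only")
  proj <- project_cohort(ev, 1000)
  expect_identical(proj$patients[proj$group == "positive"], 462L)
  expect_identical(proj$true_cases[proj$group == "positive"], 383L)
  expect_identical(sum(proj$patients), 1000L)
  expect_equal(attr(proj, "prevalence"), 197 / 433)

  # scaled counts sit within 0.5 of the exact proportion before reconciliation
  expect_true(all(abs(proj$true_cases - ev$group_true_counts * 1000 / 433)
                  <= 0.5))

  # empty groups stay empty
  expect_identical(proj$patients[proj$group == "suspicious"], 0L)
  expect_error(project_cohort(ev, 0), "cohort_n")
})

test_that("cost per detected case matches all published per-group values", {
  p <- econ_params()
  expect_equal(cost_per_true_positive(383, p), 6381)
  expect_equal(cost_per_true_positive(28, p), 87286)
  expect_equal(cost_per_true_positive(5, p), 488800)
  expect_equal(cost_per_true_positive(391, p), 6251)
  expect_equal(cost_per_true_positive(25, p), 97760)
  expect_equal(cost_per_true_positive(0, p), Inf)
  # strictly decreasing in the detected count
  expect_true(all(diff(cost_per_true_positive(1:50, p)) < 0))
})

test_that("strategy totals reproduce the published cost and time rows", {
  p <- econ_params()
  ref <- reference_econ_inputs()
  proj_int <- cohort_projection(ref$internal$groups, ref$internal$true_cases,
                                ref$internal$detected,
                                prevalence = 197 / 433)
  conv <- strategy_totals(proj_int, p, "conventional")
  expect_equal(conv$cost_rmb, 2444000)
  expect_equal(conv$time_hours, 226.4)
  tt <- strategy_totals(proj_int, p, "t1_t2_only")
  expect_equal(tt$cost_rmb, 2246000)
  expect_equal(tt$time_hours, 129.2)
  dd <- strategy_totals(proj_int, p, "darndest")
  expect_identical(dd$n_enhanced, 633L)
  expect_equal(dd$time_hours, 190.7) # (633*0.2264 + 367*0.1292) rounded

  proj_ext <- cohort_projection(ref$external$groups, ref$external$true_cases,
                                ref$external$detected,
                                prevalence = 93 / 202)
  dd_ext <- strategy_totals(proj_ext, p, "darndest")
  expect_identical(dd_ext$n_enhanced, 569L)
  expect_equal(dd_ext$time_hours, 184.5)

  # totals ordered: fused-only <= layered <= conventional
  expect_true(tt$cost_rmb <= dd$cost_rmb && dd$cost_rmb <= conv$cost_rmb)
})

test_that("currency conversion and cost ratios match published figures", {
  expect_equal(convert_currency(2444000), 340865)
  expect_equal(convert_currency(2246000), 313250)
  expect_equal(convert_currency(0), 0)
  expect_error(convert_currency(100, 0), "fx_rate")

  ref <- reference_econ_inputs()$totals
  expect_equal(cost_ratio(ref$darndest_internal_rmb, ref$conventional_rmb),
               97.03)
  expect_equal(cost_ratio(ref$darndest_external_rmb, ref$conventional_rmb),
               96.51)
  expect_equal(cost_ratio(ref$darndest_internal_rmb, ref$t1_t2_rmb), 105.58)
  expect_equal(cost_ratio(5, 5), 100)
  expect_error(cost_ratio(1, 0), "denominator")
})

test_that("econ_report assembles groups, totals and ratios coherently", {
  ref <- reference_econ_inputs()
  proj <- cohort_projection(ref$internal$groups, ref$internal$true_cases,
                            ref$internal$detected, prevalence = 197 / 433)
  rep <- econ_report(proj)
  expect_equal(rep$groups$cost_per_tp, c(6381, 87286, 488800))
  # cost_per_tp * detected reproduces the conventional cohort total
  p <- econ_params()
  exact <- p$cohort_n * p$unit_cost_enhanced / proj$detected_true
  expect_equal(exact * proj$detected_true,
               rep(p$cohort_n * p$unit_cost_enhanced, 3))
  expect_equal(rep$totals$conventional$cost_usd, 340865)
  expect_equal(rep$totals$t1_t2_only$cost_usd, 313250)
  # ratios recomputed from derived unit costs land on the published ratios
  expect_equal(unname(rep$ratios["darndest_vs_conventional"]), 97.03)
  expect_equal(unname(rep$ratios["darndest_vs_t1_t2"]), 105.58)
})

test_that("econ parameter validation rejects inconsistent pricing", {
  expect_error(econ_params(unit_cost_enhanced = 100,
                           unit_cost_unenhanced = 200), "unit_cost")
  expect_error(econ_params(fx_rate = -1), "fx_rate")
  expect_error(econ_params(cohort_n = 0.5), "cohort_n")
  expect_error(cohort_projection(c(500, 400, 99), c(1, 1, 1), c(1, 1, 1),
                                 cohort_n = 1000), "sum")
  expect_error(cohort_projection(c(500, 400, 100), c(1, 1, 1), c(2, 1, 1)),
               "detected_true")
})
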