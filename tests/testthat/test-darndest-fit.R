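test_that("fitting calibrates cutoffs and exposes the modelling interface", {
  tab <- strict_cohort(seed = 51)
  fit <- darndest(tab)
  expect_s3_class(fit, "darndest")
  cf <- coef(fit)
  expect_named(cf, c("c1", "c2", "c3"))
  expect_true(cf["c2"] <= cf["c1"])
  # calibrated c1/c3 are the Youden cutoffs of their scores
  fused <- fuse_scores(tab$score_t1wi, tab$score_t2wi)
  expect_equal(unname(cf["c1"]), youden_cutoff(fused, tab$label))
  expect_equal(unname(cf["c3"]), youden_cutoff(tab$score_t1wic, tab$label))
  # fitted rule honours the sensitivity floor when attainable
  s <- summary(fit$evaluations$darndest)
  if (isTRUE(fit$c2_search$attainable)) {
    expect_gte(s$sensitivity[["estimate"]], 90)
  }
  expect_output(print(fit), "Layered triage rule")
  expect_output(print(summary(fit)), "Paired comparisons")
})

test_that("supplied cutoffs are honoured verbatim", {
  tab <- strict_cohort(seed = 52)
  fit <- darndest(tab, c1 = 0.490, c2 = 0.197, c3 = 0.5)
  expect_equal(unname(coef(fit)), c(0.490, 0.197, 0.5))
})

test_that("predict triages new patients and residuals flag misclassification", {
  tab <- strict_cohort(seed = 53)
  fit <- darndest(tab)
  expect_identical(predict(fit), fit$outcome)
  new <- strict_cohort(seed = 54, n = 50)
  pred <- predict(fit, new)
  expect_identical(nrow(pred), 50L)
  expect_setequal(levels(pred$group), c("positive", "suspicious", "negative"))
  r <- residuals(fit)
  expect_true(all(r %in% c(-1, 0, 1)))
  expect_identical(sum(r == 1), fit$evaluations$darndest$confusion$fn)
  expect_identical(sum(r == -1), fit$evaluations$darndest$confusion$fp)
})

test_that("simulate draws cohorts calibrated to the fitted data", {
  tab <- strict_cohort(seed = 55)
  fit <- darndest(tab)
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_length(sims, 2)
  expect_identical(nrow(sims[[1]]), nrow(tab))
  expect_false(identical(sims[[1]]$score_t1wi, sims[[2]]$score_t1wi))
  # deterministic in the seed
  again <- simulate(fit, nsim = 2, seed = 9)
  expect_identical(sims, again)
})

test_that("plot method draws without error", {
  tab <- strict_cohort(seed = 56, n = 120)
  fit <- darndest(tab)
  pdf(NULL)
  on.exit(dev.off())
  expect_no_error(plot(fit))
})

test_that("pipeline bundles are byte-identical given the same config", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  cfg <- function(out) pipeline_config(
    synthetic = synthetic_config(n = 300, prevalence = 0.45),
    out_dir = out, seed = 77)
  run_pipeline(cfg(out1))
  run_pipeline(cfg(out2))
  files <- list.files(out1)
  expect_true(all(c("scores.csv", "cutoffs.json", "triage.csv",
                    "evaluation_darndest.json", "comparisons.json",
                    "econ.json", "run_log.json") %in% files))
  for (f in files) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
  }
})

test_that("pipeline with published cutoffs keeps the sensitivity dominance", {
  out <- withr::local_tempdir()
  res <- run_pipeline(pipeline_config(
    synthetic = synthetic_config(n = 433, prevalence = 197 / 433),
    c1 = 0.490, c2 = 0.197, out_dir = out, seed = 78))
  dd <- summary(res$fit$evaluations$darndest)
  tt <- summary(res$fit$evaluations$t1_t2_only)
  expect_gte(dd$sensitivity[["estimate"]], tt$sensitivity[["estimate"]])
  ev <- jsonlite::read_json(file.path(out, "evaluation_darndest.json"))
  expect_equal(ev$confusion$tp, res$fit$evaluations$darndest$confusion$tp)
})

test_that("pipeline config validation and stage error propagation", {
  expect_error(pipeline_config(), "exactly one")
  expect_error(pipeline_config(input = "x.csv",
                               synthetic = synthetic_config()), "exactly one")
  expect_error(pipeline_config(input = "x.csv", alpha = 2), "alpha")
  out <- withr::local_tempdir()
  expect_error(run_pipeline(pipeline_config(input = "no-such.csv",
                                            out_dir = out)),
               "stage 'input'")
})

test_that("a fixture cohort reproducing the published confusion flows through", {
  tab <- table_from_confusion(166, 31, 34, 202)
  path <- withr::local_tempfile(fileext = ".csv")
  write_score_table(tab, path)
  out <- withr::local_tempdir()
  res <- run_pipeline(pipeline_config(input = path, c1 = 0.5, c2 = 0.5,
                                      c3 = 0.99, out_dir = out, seed = 1))
  s <- summary(res$fit$evaluations$t1_t2_only)
  expect_equal(round_half_up(s$sensitivity[["estimate"]], 2), 84.26)
  expect_equal(round_half_up(s$specificity[["estimate"]], 2), 85.59)
  expect_equal(round_half_up(s$accuracy[["estimate"]], 2), 84.99)
  expect_equal(round_half_up(s$ppv[["estimate"]], 2), 83.00)
  expect_equal(round_half_up(s$npv[["estimate"]], 2), 86.70)
})
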