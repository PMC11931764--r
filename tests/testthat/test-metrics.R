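test_that("wald_ci reproduces published intervals and the closed form", {
  expect_equal(round_half_up(wald_ci(166, 197), 2),
               c(low = 79.18, high = 89.35))
  # closed form at p = 0.5, n = 100: 50 +/- 1.959964 * 5
  expect_equal(unname(wald_ci(50, 100)),
               c(50 - qnorm(0.975) * 5, 50 + qnorm(0.975) * 5))
  # degenerate proportion: zero width before clipping
  expect_equal(unname(wald_ci(20, 20)), c(100, 100))
  expect_error(wald_ci(1, 0), "positive")
  expect_error(wald_ci(5, 4), "successes")
})

test_that("diagnostic_summary reproduces published test-cohort rows", {
  s <- diagnostic_summary(confusion_matrix(166, 31, 34, 202))
  got <- vapply(s[c("sensitivity", "specificity", "accuracy", "ppv", "npv")],
                function(v) round_half_up(v[["estimate"]], 2), numeric(1))
  expect_equal(unname(got), c(84.26, 85.59, 84.99, 83.00, 86.70))

  ext <- diagnostic_summary(confusion_matrix(79, 14, 18, 91))
  expect_equal(round_half_up(ext$sensitivity[["estimate"]], 2), 84.95)
  expect_equal(round_half_up(ext$specificity[["estimate"]], 2), 83.49)
  expect_equal(round_half_up(ext$accuracy[["estimate"]], 2), 84.16)
  expect_equal(round_half_up(ext$sensitivity[c("low", "high")], 2),
               c(low = 77.68, high = 92.21))

  perfect <- diagnostic_summary(confusion_matrix(1, 0, 0, 1))
  for (m in c("sensitivity", "specificity", "accuracy", "ppv", "npv")) {
    expect_equal(perfect[[m]][["estimate"]], 100)
  }
})

test_that("zero-denominator metrics are flagged undefined, not fabricated", {
  s <- diagnostic_summary(confusion_matrix(0, 0, 3, 7)) # no true cases
  expect_true(is.na(s$sensitivity[["estimate"]]))
  expect_false(is.na(s$specificity[["estimate"]]))
  s2 <- diagnostic_summary(confusion_matrix(2, 0, 3, 0)) # nobody called negative
  expect_true(is.na(s2$npv[["estimate"]]))
  expect_false(is.na(s2$ppv[["estimate"]]))
})

test_that("diagnostic identities hold before rounding", {
  set.seed(31)
  for (i in 1:20) {
    cm <- confusion_matrix(sample(1:50, 1), sample(1:50, 1),
                           sample(1:50, 1), sample(1:50, 1))
    s <- diagnostic_summary(cm)
    n <- cm$tp + cm$fn + cm$fp + cm$tn
    # accuracy * n = tp + tn exactly
    expect_equal(s$accuracy[["estimate"]] / 100 * n, cm$tp + cm$tn)
    # PPV from sensitivity, specificity and prevalence by Bayes' rule
    se <- s$sensitivity[["estimate"]] / 100
    sp <- s$specificity[["estimate"]] / 100
    prev <- (cm$tp + cm$fn) / n
    bayes <- se * prev / (se * prev + (1 - sp) * (1 - prev))
    expect_equal(s$ppv[["estimate"]] / 100, bayes, tolerance = 1e-12)
  }
})

test_that("McNemar Z matches closed forms and is antisymmetric", {
  # b = c: symmetric, Z = 0, p = 1
  lab <- rep(1, 10)
  a <- c(rep(1, 5), rep(0, 5))
  b <- c(rep(0, 5), rep(1, 5))
  t0 <- mcnemar_test(lab, a, b)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)

  # b = 10, c = 0
  lab <- rep(1, 10)
  t1 <- mcnemar_test(lab, rep(1, 10), rep(0, 10))
  expect_equal(t1$statistic, 10 / sqrt(10), tolerance = 1e-12)
  expect_equal(round_half_up(t1$statistic, 4), 3.1623)
  t1c <- mcnemar_test(lab, rep(1, 10), rep(0, 10), correction = TRUE)
  expect_equal(round_half_up(t1c$statistic, 4), 2.8460)

  # antisymmetry and agreement with the chi-square McNemar (Z^2 = X^2)
  set.seed(7)
  labels <- rbinom(80, 1, 0.5)
  ca <- rbinom(80, 1, 0.5)
  cb <- rbinom(80, 1, 0.5)
  tab_ab <- mcnemar_test(labels, ca, cb)
  tab_ba <- mcnemar_test(labels, cb, ca)
  expect_equal(tab_ab$statistic, -tab_ba$statistic)
  expect_equal(tab_ab$p_value, tab_ba$p_value)
  ref <- stats::mcnemar.test(table(factor(ca == labels, c(FALSE, TRUE)),
                                   factor(cb == labels, c(FALSE, TRUE))),
                             correct = FALSE)
  expect_equal(tab_ab$statistic^2, unname(ref$statistic))
  expect_equal(tab_ab$p_value, ref$p.value)

  expect_error(mcnemar_test(labels, ca, cb[-1]), "equal length")
})

test_that("significance flag follows the Bonferroni alpha", {
  lab <- rep(1, 30)
  t1 <- mcnemar_test(lab, rep(1, 30), rep(0, 30)) # p ~ 4e-8
  expect_true(t1$significant)
  expect_equal(t1$alpha, 0.05 / 3)
  t2 <- mcnemar_test(lab, rep(1, 30), rep(0, 30), alpha = 1e-10)
  expect_false(t2$significant)
})

test_that("roc_auc matches trivial cases and the pair-count oracle", {
  r <- roc_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(0:1, 5))$auc, 0.5)

  set.seed(19)
  for (i in 1:5) {
    scores <- round(runif(60), 2) # rounding forces ties
    labels <- rbinom(60, 1, 0.5)
    if (length(unique(labels)) < 2) next
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, brute_auc(scores, labels), tolerance = 1e-12)
    # trapezoidal area equals the Mann-Whitney AUC
    trap <- sum(diff(r$fpr) * (utils::head(r$tpr, -1) + utils::tail(r$tpr, -1)) / 2)
    expect_equal(trap, r$auc, tolerance = 1e-12)
    # curve monotone
    expect_true(all(diff(r$tpr) >= 0) && all(diff(r$fpr) >= 0))
    # negation flips the AUC
    expect_equal(roc_auc(-scores, labels)$auc, 1 - r$auc, tolerance = 1e-12)
  }
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")
})

test_that("AUC and DeLong p agree with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  scores_a <- runif(120)
  labels <- rbinom(120, 1, 0.45)
  scores_b <- plogis(qlogis(scores_a) + rnorm(120))
  r <- roc_auc(scores_a, labels)
  pr <- pROC::roc(labels, scores_a, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
  expect_equal(c(r$auc_ci_low, r$auc_ci_high), ci[c(1, 3)], tolerance = 1e-9)

  dl <- delong_compare(scores_a, scores_b, labels)
  ref <- pROC::roc.test(pr, pROC::roc(labels, scores_b, quiet = TRUE,
                                      direction = "<"), method = "delong",
                        paired = TRUE)
  expect_equal(dl$p_value, ref$p.value, tolerance = 1e-9)
  expect_equal(abs(dl$statistic), abs(unname(ref$statistic)), tolerance = 1e-9)
})

test_that("DeLong variance tracks the leave-one-out jackknife", {
  set.seed(29)
  for (i in 1:4) {
    scores <- runif(20)
    labels <- c(rep(1, 8), rep(0, 12))
    r <- roc_auc(scores, labels)
    jack <- jackknife_auc_var(scores, labels)
    expect_equal(r$var_auc, jack, tolerance = 0.15)
  }
})

test_that("identical score vectors give zero AUC difference and p = 1", {
  set.seed(37)
  s <- runif(40)
  lab <- rbinom(40, 1, 0.5)
  d <- delong_compare(s, s, lab)
  expect_equal(d$statistic, 0)
  expect_equal(d$auc_a, d$auc_b)
  expect_equal(d$p_value, 1)
})

test_that("DeLong test holds its size under an uninformative null", {
  set.seed(41)
  reject <- logical(1000)
  for (i in seq_along(reject)) {
    lab <- rbinom(200, 1, 0.5)
    if (length(unique(lab)) < 2) lab[1:2] <- 0:1
    reject[i] <- delong_compare(runif(200), runif(200), lab,
                                alpha = 0.05)$p_value < 0.05
  }
  expect_lt(abs(mean(reject) - 0.05), 0.02)
})
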