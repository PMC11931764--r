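#' Fit the layered contrast-sparing triage rule
#'
#' `darndest()` calibrates the layered follow-up tactic on a per-patient
#' score table and returns a fitted rule. Every patient is first assessed by
#' the fused unenhanced-sequence score (`0.5 * T1WI + 0.5 * T2WI`); those at
#' or above the first-level cutoff `c1` form the positive group. The
#' remaining patients are split at the referral cutoff `c2`: the suspicious
#' group receives a contrast-enhanced scan and is adjudicated by the
#' post-contrast (T1WIC) model at cutoff `c3`, while the negative group is
#' followed with unenhanced MRI only.
#'
#' Cutoffs left `NULL` are calibrated on `data`: `c1` is the Youden-index
#' cutoff of the fused score, `c3` the Youden-index cutoff of the T1WIC
#' score, and `c2` the largest referral cutoff keeping the rule's overall
#' sensitivity at or above `sens_floor` (see [select_secondary_cutoff()]).
#' If no second level is needed (the first level alone meets the floor),
#' `c2` is set to `c1` and the rule collapses to the fused model.
#'
#' @param data a `"score_table"` (or coercible data frame) with both label
#'   classes present.
#' @param c1,c2,c3 optional fixed cutoffs; any subset may be supplied (e.g.
#'   the published internal pair `c1 = 0.490`, `c2 = 0.197`).
#' @param sens_floor sensitivity floor for the `c2` search (default 0.90).
#' @param conf_level confidence level for all intervals (default 0.95).
#' @param alpha significance threshold for the paired tests; default 0.05/3,
#'   Bonferroni over the three pairwise model comparisons.
#' @param mcnemar_correction use the continuity-corrected McNemar Z.
#' @return an object of class `"darndest"` with components `cutoffs`
#'   ([cutoff_set()]), `data`, `outcome` (per-patient [darndest_assign()]
#'   table), `evaluations` (one [evaluate_strategy()] result per strategy),
#'   `c2_search` (attributes of the `c2` selection), and the call.
#' @examples
#' cohort <- generate_cohort(synthetic_config(seed = 7))
#' fit <- darndest(cohort)
#' fit
#' coef(fit)
#' @export
darndest <- function(data, c1 = NULL, c2 = NULL, c3 = NULL,
                     sens_floor = 0.90, conf_level = 0.95,
                     alpha = 0.05 / 3, mcnemar_correction = FALSE) {
  cl <- match.call()
  data <- as_score_table(data)
  if (length(unique(data$label)) < 2) {
    stop("both label classes must be present to fit the rule", call. = FALSE)
  }
  fused <- fuse_scores(data$score_t1wi, data$score_t2wi)
  if (is.null(c1)) c1 <- youden_cutoff(fused, data$label)
  if (is.null(c3)) c3 <- youden_cutoff(data$score_t1wic, data$label)
  c2_search <- NULL
  if (is.null(c2)) {
    sel <- select_secondary_cutoff(data, c1, c3, sens_floor)
    c2_search <- list(needed = attr(sel, "needed"),
                      attainable = attr(sel, "attainable"))
    c2 <- if (isTRUE(c2_search$needed)) as.numeric(sel) else c1
  }
  cutoffs <- cutoff_set(c1 = c1, c2 = c2, c3 = c3, sens_floor = sens_floor)
  outcome <- darndest_assign(data, cutoffs)
  evaluations <- lapply(
    stats::setNames(nm = c("darndest", "t1_t2_only", "t1wic_only",
                           "conventional")),
    function(s) evaluate_strategy(data, cutoffs, s, level = conf_level))
  structure(list(cutoffs = cutoffs, data = data, outcome = outcome,
                 evaluations = evaluations, c2_search = c2_search,
                 conf_level = conf_level, alpha = alpha,
                 mcnemar_correction = mcnemar_correction, call = cl),
            class = "darndest")
}

#' @export
print.darndest <- function(x, ...) {
  cat("Layered triage rule\n\nCall:\n  ")
  print(x$call)
  cat("\n")
  print(x$cutoffs)
  ev <- x$evaluations$darndest
  cat(sprintf("\nGroups: %s\n",
              paste(sprintf("%s %d", names(ev$group_counts), ev$group_counts),
                    collapse = ", ")))
  s <- ev$summary
  cat(sprintf("Sensitivity %.2f%%, specificity %.2f%%, accuracy %.2f%% (n = %d)\n",
              round_half_up(s$sensitivity["estimate"], 2),
              round_half_up(s$specificity["estimate"], 2),
              round_half_up(s$accuracy["estimate"], 2), ev$n))
  invisible(x)
}

#' @export
coef.darndest <- function(object, ...) {
  with(object$cutoffs, c(c1 = c1, c2 = c2, c3 = c3))
}

#' Triage new patients with a fitted rule
#'
#' @param object a fitted `"darndest"` rule.
#' @param newdata a score table; defaults to the calibration data.
#' @param ... unused.
#' @return the per-patient `"triage_outcome"` table.
#' @export
predict.darndest <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$outcome)
  darndest_assign(as_score_table(newdata), object$cutoffs)
}

#' @export
residuals.darndest <- function(object, ...) {
  object$data$label - object$outcome$final_call
}

#' Summarise a fitted triage rule
#'
#' Diagnostic summaries of the layered rule and of the fused-only and
#' T1WIC-only comparators, pairwise McNemar Z tests of their correctness,
#' and DeLong paired comparisons of the underlying score AUCs.
#'
#' @param object a fitted `"darndest"` rule.
#' @param ... unused.
#' @return an object of class `"summary.darndest"`.
#' @export
summary.darndest <- function(object, ...) {
  d <- object$data
  fused <- object$outcome$fused
  calls <- list(
    darndest = object$outcome$final_call,
    t1_t2_only = as.integer(fused >= object$cutoffs$c1),
    t1wic_only = as.integer(d$score_t1wic >= object$cutoffs$c3)
  )
  pairs <- utils::combn(names(calls), 2, simplify = FALSE)
  mcnemar <- lapply(pairs, function(p) {
    mcnemar_test(d$label, calls[[p[1]]], calls[[p[2]]],
                 correction = object$mcnemar_correction,
                 alpha = object$alpha)
  })
  names(mcnemar) <- vapply(pairs, paste, "", collapse = " vs ")
  scores <- list(t1wi = d$score_t1wi, t2wi = d$score_t2wi,
                 t1wic = d$score_t1wic, t1_t2 = fused)
  roc <- lapply(scores, roc_auc, labels = d$label, level = object$conf_level)
  delong <- list(
    "t1wic vs t1wi" = delong_compare(d$score_t1wic, d$score_t1wi, d$label,
                                     alpha = object$alpha),
    "t1wic vs t2wi" = delong_compare(d$score_t1wic, d$score_t2wi, d$label,
                                     alpha = object$alpha),
    "t1wic vs t1_t2" = delong_compare(d$score_t1wic, fused, d$label,
                                      alpha = object$alpha)
  )
  structure(list(cutoffs = object$cutoffs,
                 evaluations = object$evaluations[c("darndest", "t1_t2_only",
                                                    "t1wic_only")],
                 mcnemar = mcnemar, roc = roc, delong = delong,
                 alpha = object$alpha),
            class = "summary.darndest")
}

#' @export
print.summary.darndest <- function(x, ...) {
  print(x$cutoffs)
  for (s in names(x$evaluations)) {
    cat("\n--", s, "--\n")
    print(x$evaluations[[s]]$summary)
  }
  cat("\nROC AUCs:\n")
  for (m in names(x$roc)) {
    r <- x$roc[[m]]
    cat(sprintf("  %-6s AUC %.4f (%.4f-%.4f)\n", m, r$auc, r$auc_ci_low,
                r$auc_ci_high))
  }
  cat("\nPaired comparisons (alpha =", format(x$alpha, digits = 4), "):\n")
  for (nm in names(x$mcnemar)) {
    t <- x$mcnemar[[nm]]
    cat(sprintf("  McNemar %-24s Z = %7.4f, p = %.4f\n", nm, t$statistic,
                t$p_value))
  }
  for (nm in names(x$delong)) {
    t <- x$delong[[nm]]
    cat(sprintf("  DeLong  %-24s Z = %7.4f, p = %.4f\n", nm, t$statistic,
                t$p_value))
  }
  invisible(x)
}

#' Plot ROC curves of a fitted rule's underlying scores
#'
#' Draws the ROC curves of the three sequence scores and the fused score,
#' with AUCs in the legend and the fitted cutoffs marked on their curves.
#'
#' @param x a fitted `"darndest"` rule.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.darndest <- function(x, ...) {
  d <- x$data
  fused <- x$outcome$fused
  scores <- list(t1_t2 = fused, t1wic = d$score_t1wic,
                 t1wi = d$score_t1wi, t2wi = d$score_t2wi)
  cols <- c(t1_t2 = "black", t1wic = "firebrick", t1wi = "steelblue",
            t2wi = "darkgreen")
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3, col = "grey",
                 xlab = "False-positive rate", ylab = "True-positive rate",
                 main = "ROC of sequence scores", ...)
  leg <- character(0)
  for (m in names(scores)) {
    r <- roc_auc(scores[[m]], d$label)
    graphics::lines(r$fpr, r$tpr, col = cols[m], lwd = 2)
    leg <- c(leg, sprintf("%s (AUC %.3f)", m, r$auc))
  }
  graphics::legend("bottomright", legend = leg, col = cols, lwd = 2,
                   bty = "n")
  invisible(x)
}

#' Simulate score cohorts calibrated to a fitted rule
#'
#' Draws synthetic cohorts from the binormal generator calibrated to the
#' calibration data's empirical prevalence and per-score AUCs, so simulated
#' cohorts look (marginally) like the data the rule was fitted on.
#'
#' @param object a fitted `"darndest"` rule.
#' @param nsim number of cohorts.
#' @param seed integer seed; successive cohorts use `seed + 0:(nsim-1)`.
#' @param n cohort size (default: size of the calibration data).
#' @param correlation within-class latent correlation (default 0.5).
#' @param ... unused.
#' @return a list of `nsim` score tables.
#' @export
simulate.darndest <- function(object, nsim = 1, seed = 1L, n = NULL,
                              correlation = 0.5, ...) {
  d <- object$data
  aucs <- vapply(list(t1wi = d$score_t1wi, t2wi = d$score_t2wi,
                      t1wic = d$score_t1wic),
                 function(s) roc_auc(s, d$label)$auc, numeric(1))
  aucs <- pmin(pmax(aucs, 0.501), 0.999) # binormal generator needs (0.5, 1)
  if (is.null(n)) n <- nrow(d)
  lapply(seq_len(nsim), function(i) {
    generate_cohort(synthetic_config(
      n = n, prevalence = mean(d$label == 1), auc_targets = aucs,
      correlation = correlation, seed = as.integer(seed) + i - 1L))
  })
}
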