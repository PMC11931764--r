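#' Round half away from zero
#'
#' Display convention used throughout the reports: percentages to two
#' decimals, currency to whole units, hours to one decimal, always rounding
#' halves away from zero (unlike base `round()`'s round-half-even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Wald confidence interval for a binomial proportion
#'
#' Normal-approximation interval `p +/- z * sqrt(p(1-p)/n)`, clipped to
#' \[0, 100\] and returned on the percentage scale. This is the interval the
#' diagnostic summaries report.
#'
#' @param successes number of successes (0..n).
#' @param n number of trials (>= 1).
#' @param level confidence level (default 0.95).
#' @return numeric `c(low, high)` in percent (unrounded; display rounds to
#'   two decimals).
#' @examples
#' round_half_up(wald_ci(166, 197), 2) # 79.18 89.35
#' @export
wald_ci <- function(successes, n, level = 0.95) {
  if (length(n) != 1 || n < 1) stop("n must be a positive integer", call. = FALSE)
  if (successes < 0 || successes > n) {
    stop("successes must lie in [0, n]", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- successes / n
  half <- z * sqrt(p * (1 - p) / n)
  stats::setNames(100 * pmin(1, pmax(0, c(p - half, p + half))),
                  c("low", "high"))
}

metric_with_ci <- function(successes, n, level) {
  if (n < 1) {
    return(c(estimate = NA_real_, low = NA_real_, high = NA_real_))
  }
  ci <- wald_ci(successes, n, level)
  c(estimate = 100 * successes / n, low = unname(ci[1]), high = unname(ci[2]))
}

#' Diagnostic performance summary with confidence intervals
#'
#' Sensitivity, specificity, accuracy, PPV and NPV (percent) from a 2x2
#' confusion matrix, each with a Wald 95% confidence interval. A metric whose
#' denominator is zero is reported as `NA` (flagged undefined) rather than
#' fabricated.
#'
#' @param cm a [confusion_matrix()].
#' @param level confidence level for the intervals.
#' @return an object of class `"diagnostic_summary"`: a list with one
#'   `c(estimate, low, high)` entry per metric (raw, unrounded percentages)
#'   plus `n_pos`, `n_neg` and the source matrix.
#' @examples
#' diagnostic_summary(confusion_matrix(166, 31, 34, 202))
#' @export
diagnostic_summary <- function(cm, level = 0.95) {
  if (!inherits(cm, "confusion_matrix")) {
    stop("cm must be a confusion_matrix", call. = FALSE)
  }
  n <- cm$tp + cm$fn + cm$fp + cm$tn
  out <- list(
    sensitivity = metric_with_ci(cm$tp, cm$tp + cm$fn, level),
    specificity = metric_with_ci(cm$tn, cm$fp + cm$tn, level),
    accuracy    = metric_with_ci(cm$tp + cm$tn, n, level),
    ppv         = metric_with_ci(cm$tp, cm$tp + cm$fp, level),
    npv         = metric_with_ci(cm$tn, cm$fn + cm$tn, level),
    n_pos = cm$tp + cm$fn,
    n_neg = cm$fp + cm$tn,
    confusion = cm,
    level = level
  )
  structure(out, class = "diagnostic_summary")
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  cat(sprintf("Diagnostic summary (%d recurrent, %d recurrence-free)\n",
              x$n_pos, x$n_neg))
  for (m in c("sensitivity", "specificity", "accuracy", "ppv", "npv")) {
    v <- x[[m]]
    if (anyNA(v)) {
      cat(sprintf("  %-12s undefined (zero denominator)\n", m))
    } else {
      cat(sprintf("  %-12s %6.2f%% (%.2f, %.2f)\n", m,
                  round_half_up(v["estimate"], 2),
                  round_half_up(v["low"], 2), round_half_up(v["high"], 2)))
    }
  }
  invisible(x)
}

#' McNemar's Z test for paired binary classifiers
#'
#' Compares two classifiers on the same patients through their per-patient
#' correctness indicators (call equals label). With `b` = patients method A
#' gets right and B wrong, `c` = the reverse, the statistic is
#' `Z = (b - c) / sqrt(b + c)` (continuity-corrected variant shrinks
#' `|b - c|` by 1), with a two-sided normal p-value. `b + c = 0` gives
#' statistic 0 and p = 1.
#'
#' @param labels binary ground truth.
#' @param calls_a,calls_b binary calls of the two methods, same length.
#' @param correction apply the continuity correction (default FALSE).
#' @param alpha significance threshold; default 0.05/3, the Bonferroni level
#'   for three pairwise model comparisons.
#' @return an object of class `"paired_test"` with fields `statistic`,
#'   `p_value`, `alpha`, `significant`, `b`, `c`.
#' @export
mcnemar_test <- function(labels, calls_a, calls_b, correction = FALSE,
                         alpha = 0.05 / 3) {
  if (length(labels) != length(calls_a) || length(labels) != length(calls_b)) {
    stop("labels, calls_a and calls_b must have equal length", call. = FALSE)
  }
  ok_a <- calls_a == labels
  ok_b <- calls_b == labels
  b <- sum(ok_a & !ok_b)
  cc <- sum(!ok_a & ok_b)
  if (b + cc == 0) {
    z <- 0
    p <- 1
  } else {
    num <- if (correction) sign(b - cc) * max(abs(b - cc) - 1, 0) else b - cc
    z <- num / sqrt(b + cc)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(statistic = z, p_value = p, alpha = alpha,
                 significant = p < alpha, b = b, c = cc,
                 method = if (correction) "McNemar Z (continuity-corrected)"
                          else "McNemar Z"),
            class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.null(x$auc_a)) {
    cat(sprintf("  AUC A = %.4f, AUC B = %.4f, difference = %.4f\n",
                x$auc_a, x$auc_b, x$auc_a - x$auc_b))
  }
  if (!is.null(x$b)) cat(sprintf("  discordant pairs: b = %d, c = %d\n", x$b, x$c))
  cat(sprintf("  Z = %.4f, p = %.4g (%ssignificant at alpha = %.4f)\n",
              x$statistic, x$p_value, if (x$significant) "" else "not ",
              x$alpha))
  invisible(x)
}

# Placement values (DeLong components) of one score vector.
# V10[i] = fraction of controls below case i (ties count 1/2); V01[j]
# symmetric. Computed from midranks in O(n log n).
placement_values <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  m <- length(x)
  n <- length(y)
  if (m == 0 || n == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(c(x, y), ties.method = "average")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  v10 <- (r[seq_len(m)] - rx) / n
  v01 <- 1 - (r[m + seq_len(n)] - ry) / m
  list(v10 = v10, v01 = v01, auc = mean(v10), m = m, n = n)
}

#' ROC curve and AUC
#'
#' Thresholds are the unique observed scores (descending) with call rule
#' "positive if score >= t"; the AUC is the tie-corrected Mann-Whitney
#' probability (ties count 1/2), which equals the trapezoidal area under the
#' curve. The confidence interval uses the DeLong placement-value variance of
#' the single curve.
#'
#' @param scores numeric score vector.
#' @param labels binary labels; both classes must be present.
#' @param level confidence level for the AUC interval.
#' @return an object of class `"roc_result"`: descending `thresholds` (with a
#'   leading `Inf` for the (0,0) corner), `tpr`, `fpr`, `auc`, `auc_ci_low`,
#'   `auc_ci_high`, `var_auc`.
#' @export
roc_auc <- function(scores, labels, level = 0.95) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1)) || length(unique(labels)) < 2) {
    stop("labels must be binary with both classes present", call. = FALSE)
  }
  pv <- placement_values(scores, labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  last <- cumsum(rle(s)$lengths) # last index of each tie group
  tpr <- cumsum(l == 1)[last] / pv$m
  fpr <- cumsum(l == 0)[last] / pv$n
  var_auc <- stats::var(pv$v10) / pv$m + stats::var(pv$v01) / pv$n
  if (is.na(var_auc)) var_auc <- 0 # single case or control
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(var_auc)
  structure(list(thresholds = c(Inf, s[last]),
                 tpr = c(0, tpr), fpr = c(0, fpr),
                 auc = pv$auc,
                 auc_ci_low = max(0, pv$auc - half),
                 auc_ci_high = min(1, pv$auc + half),
                 var_auc = var_auc,
                 n_pos = pv$m, n_neg = pv$n),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (95%% CI %.4f-%.4f), %d cases / %d controls\n",
              x$auc, x$auc_ci_low, x$auc_ci_high, x$n_pos, x$n_neg))
  invisible(x)
}

#' DeLong test for two correlated AUCs
#'
#' Paired comparison of the areas under two ROC curves measured on the same
#' patients. The variance of the AUC difference comes from the per-class
#' placement-value components of each curve and their covariance; the p-value
#' is two-sided normal.
#'
#' @param scores_a,scores_b score vectors of the two models, same patients.
#' @param labels binary labels; both classes must be present.
#' @param alpha significance threshold (default 0.05/3).
#' @return a `"paired_test"` with `auc_a`, `auc_b`, `statistic` (Z of the
#'   difference), `p_value`, `var_diff`.
#' @export
delong_compare <- function(scores_a, scores_b, labels, alpha = 0.05 / 3) {
  if (length(scores_a) != length(labels) || length(scores_b) != length(labels)) {
    stop("score vectors and labels must have equal length", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1)) || length(unique(labels)) < 2) {
    stop("labels must be binary with both classes present", call. = FALSE)
  }
  pa <- placement_values(scores_a, labels)
  pb <- placement_values(scores_b, labels)
  # var of the difference: S10 and S01 2x2 component matrices collapse to
  # the variance of the per-observation placement differences
  v10 <- if (pa$m > 1) stats::var(pa$v10 - pb$v10) / pa$m else 0
  v01 <- if (pa$n > 1) stats::var(pa$v01 - pb$v01) / pa$n else 0
  var_diff <- v10 + v01
  diff <- pa$auc - pb$auc
  if (var_diff <= 0) {
    z <- 0
    p <- if (diff == 0) 1 else NA_real_
  } else {
    z <- diff / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(statistic = z, p_value = p, alpha = alpha,
                 significant = isTRUE(p < alpha),
                 auc_a = pa$auc, auc_b = pb$auc, var_diff = var_diff,
                 method = "DeLong paired AUC comparison"),
            class = "paired_test")
}
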