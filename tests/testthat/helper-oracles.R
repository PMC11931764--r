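# Independent brute-force oracles used to cross-check the implementation.

# O(m*n) pair-count AUC: mean over all case/control pairs of
# [case > control] + 0.5 [case == control]
brute_auc <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  mean(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}

# exhaustive Youden sweep over every unique score, call rule score >= t,
# smallest maximiser
brute_youden <- function(scores, labels) {
  ts <- sort(unique(scores))
  j <- vapply(ts, function(t) {
    calls <- as.integer(scores >= t)
    sens <- sum(calls == 1 & labels == 1) / sum(labels == 1)
    spec <- sum(calls == 0 & labels == 0) / sum(labels == 0)
    sens + spec - 1
  }, numeric(1))
  ts[which(j >= max(j) - 1e-12)][1]
}

# leave-one-out jackknife variance of the Mann-Whitney AUC
jackknife_auc_var <- function(scores, labels) {
  n <- length(scores)
  theta <- vapply(seq_len(n), function(i) {
    brute_auc(scores[-i], labels[-i])
  }, numeric(1))
  (n - 1) / n * sum((theta - mean(theta))^2)
}

# score table realising a given confusion quadruple for the fused-score rule
# at c1 = 0.5 (called rows fused 0.9, uncalled 0.1); t1wic constant
table_from_confusion <- function(tp, fn, fp, tn, t1wic = 0.5) {
  n <- tp + fn + fp + tn
  label <- c(rep(1, tp), rep(1, fn), rep(0, fp), rep(0, tn))
  hi <- c(rep(TRUE, tp), rep(FALSE, fn), rep(TRUE, fp), rep(FALSE, tn))
  s <- ifelse(hi, 0.9, 0.1)
  score_table(sprintf("P%04d", seq_len(n)), label, s, s, rep(t1wic, n))
}

strict_cohort <- function(seed, n = 400, prevalence = 0.45) {
  generate_cohort(synthetic_config(n = n, prevalence = prevalence,
                                   seed = seed))
}
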