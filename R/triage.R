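#' Assign patients to triage groups under the layered rule
#'
#' Applies the layered tactic to each row of a score table. With
#' `fused = fuse_scores(score_t1wi, score_t2wi)`:
#' * `fused >= c1`: **positive** group — enhanced scan, final call 1 (no
#'   adjudication; positives are acted on directly);
#' * `c2 <= fused < c1`: **suspicious** group — enhanced scan, final call
#'   `score_t1wic >= c3`;
#' * `fused < c2`: **negative** group — unenhanced scan only, final call 0.
#'
#' Boundary scores equal to a cutoff count as positive/suspicious (">=" rule
#' module-wide).
#'
#' @param table a `"score_table"` (a single row works too).
#' @param cutoffs a [cutoff_set()].
#' @return a data frame of class `"triage_outcome"`: `patient_id`, `group`
#'   (factor positive/suspicious/negative), `mri_mode`
#'   (enhanced/unenhanced), `final_call` (0/1), plus the fused score.
#' @export
darndest_assign <- function(table, cutoffs) {
  table <- as_score_table(table)
  if (!inherits(cutoffs, "cutoff_set")) {
    stop("cutoffs must be a cutoff_set", call. = FALSE)
  }
  fused <- fuse_scores(table$score_t1wi, table$score_t2wi)
  group <- ifelse(fused >= cutoffs$c1, "positive",
                  ifelse(fused >= cutoffs$c2, "suspicious", "negative"))
  final_call <- ifelse(group == "positive", 1L,
                       ifelse(group == "suspicious",
                              as.integer(table$score_t1wic >= cutoffs$c3), 0L))
  out <- data.frame(
    patient_id = table$patient_id,
    group = factor(group, levels = c("positive", "suspicious", "negative")),
    mri_mode = ifelse(group == "negative", "unenhanced", "enhanced"),
    final_call = final_call,
    fused = fused,
    stringsAsFactors = FALSE
  )
  structure(out, class = c("triage_outcome", "data.frame"))
}

strategy_names <- c("darndest", "t1_t2_only", "t1wic_only", "conventional")

#' Evaluate a follow-up strategy on a score table
#'
#' Strategies:
#' * `"darndest"`: the layered rule of [darndest_assign()]; positive and
#'   suspicious patients get the enhanced scan.
#' * `"t1_t2_only"`: positive iff fused score `>= c1`; nobody gets the
#'   enhanced scan.
#' * `"t1wic_only"`: positive iff T1WIC score `>= c3`; everybody gets the
#'   enhanced scan.
#' * `"conventional"`: everybody gets the enhanced scan; no model calls are
#'   made, so the evaluation carries group sizes for cost/time modelling
#'   only and asking it for diagnostics is an error.
#'
#' @param table a `"score_table"` with both classes present.
#' @param cutoffs a [cutoff_set()].
#' @param strategy one of `"darndest"`, `"t1_t2_only"`, `"t1wic_only"`,
#'   `"conventional"`.
#' @param level confidence level for the diagnostic summary.
#' @return an object of class `"strategy_evaluation"`: strategy name,
#'   confusion matrix and [diagnostic_summary()] (absent for
#'   `"conventional"`), per-group patient counts, true-case counts and
#'   detected (true-positive) counts, `n`, `n_enhanced`, `n_unenhanced`.
#' @export
evaluate_strategy <- function(table, cutoffs,
                              strategy = c("darndest", "t1_t2_only",
                                           "t1wic_only", "conventional"),
                              level = 0.95) {
  strategy <- match.arg(strategy)
  table <- as_score_table(table)
  if (strategy != "conventional" && length(unique(table$label)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  n <- nrow(table)
  fused <- fuse_scores(table$score_t1wi, table$score_t2wi)
  lab <- table$label

  groups <- c("positive", "suspicious", "negative")
  zero <- stats::setNames(integer(3), groups)

  if (strategy == "conventional") {
    ev <- list(strategy_name = strategy, confusion = NULL, summary = NULL,
               group_counts = zero, group_true_counts = zero,
               group_detected_counts = zero,
               n = n, n_enhanced = n, n_unenhanced = 0L)
    return(structure(ev, class = "strategy_evaluation"))
  }

  if (strategy == "darndest") {
    out <- darndest_assign(table, cutoffs)
    calls <- out$final_call
    grp <- out$group
    detected <- stats::setNames(as.integer(
      tapply(lab == 1 & calls == 1, grp, sum, default = 0L)), groups)
    n_enh <- sum(out$mri_mode == "enhanced")
  } else if (strategy == "t1_t2_only") {
    calls <- as.integer(fused >= cutoffs$c1)
    grp <- factor(ifelse(calls == 1, "positive", "negative"), levels = groups)
    detected <- stats::setNames(as.integer(
      tapply(lab == 1 & calls == 1, grp, sum, default = 0L)), groups)
    n_enh <- 0L
  } else { # t1wic_only
    calls <- as.integer(table$score_t1wic >= cutoffs$c3)
    grp <- factor(ifelse(calls == 1, "positive", "negative"), levels = groups)
    detected <- stats::setNames(as.integer(
      tapply(lab == 1 & calls == 1, grp, sum, default = 0L)), groups)
    n_enh <- n
  }

  cm <- confusion_from_calls(lab, calls)
  ev <- list(
    strategy_name = strategy,
    confusion = cm,
    summary = diagnostic_summary(cm, level = level),
    group_counts = stats::setNames(as.integer(table(grp)), groups),
    group_true_counts = stats::setNames(as.integer(
      tapply(lab == 1, grp, sum, default = 0L)), groups),
    group_detected_counts = detected,
    n = n, n_enhanced = as.integer(n_enh),
    n_unenhanced = as.integer(n - n_enh)
  )
  structure(ev, class = "strategy_evaluation")
}

#' @export
summary.strategy_evaluation <- function(object, ...) {
  if (is.null(object$summary)) {
    stop("diagnostics are not defined for the conventional strategy ",
         "(no model calls are made); it supports cost/time modelling only",
         call. = FALSE)
  }
  object$summary
}

#' @export
print.strategy_evaluation <- function(x, ...) {
  cat(sprintf("Strategy '%s' on %d patients (%d enhanced / %d unenhanced scans)\n",
              x$strategy_name, x$n, x$n_enhanced, x$n_unenhanced))
  cat("  groups:",
      paste(sprintf("%s %d (true %d, detected %d)", names(x$group_counts),
                    x$group_counts, x$group_true_counts,
                    x$group_detected_counts), collapse = "; "), "\n")
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}
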