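#' Fuse the two unenhanced-sequence scores
#'
#' The fused ("T1_T2") score is the equal-weight average
#' `0.5 * t1 + 0.5 * t2` of the T1-weighted and T2-weighted model scores.
#'
#' @param t1,t2 numeric scores in \[0, 1\] (vectorised, recycled to common
#'   length).
#' @return the fused score, always in \[0, 1\].
#' @examples
#' fuse_scores(0.4, 0.6) # 0.5
#' @export
fuse_scores <- function(t1, t2) {
  if (any(t1 < 0 | t1 > 1) || any(t2 < 0 | t2 > 1)) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  0.5 * t1 + 0.5 * t2
}

#' Youden-index optimal cutoff
#'
#' Over candidate thresholds equal to the unique observed scores, with call
#' rule "positive if score >= t", returns the threshold maximising
#' `J = sensitivity + specificity - 1`. Ties are broken by the smallest
#' maximising threshold, which maximises sensitivity at equal J.
#'
#' @param scores numeric score vector.
#' @param labels binary labels; both classes must be present.
#' @return the optimal threshold (one of the observed scores).
#' @examples
#' youden_cutoff(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)) # 0.8
#' @export
youden_cutoff <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1)) || length(unique(labels)) < 2) {
    stop("labels must be binary with both classes present", call. = FALSE)
  }
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  last <- cumsum(rle(s)$lengths)
  sens <- cumsum(l == 1)[last] / npos
  spec <- 1 - cumsum(l == 0)[last] / nneg
  j <- sens + spec - 1
  best <- max(j)
  candidates <- s[last][j >= best - 1e-12]
  min(candidates)
}

#' Construct the triage cutoff set
#'
#' The three thresholds that parameterise the layered rule: `c1`, the
#' first-level cutoff on the fused score (at or above: positive group);
#' `c2 <= c1`, the referral cutoff on the fused score (at or above but below
#' `c1`: suspicious group, referred for an enhanced scan); `c3`, the
#' adjudication cutoff on the post-contrast (T1WIC) score applied inside the
#' suspicious group.
#'
#' @param c1,c2,c3 thresholds in \[0, 1\] with `c2 <= c1`.
#' @param sens_floor the sensitivity floor used when selecting `c2`
#'   (default 0.90); carried for provenance.
#' @return an object of class `"cutoff_set"`.
#' @export
cutoff_set <- function(c1, c2, c3, sens_floor = 0.90) {
  vals <- c(c1 = c1, c2 = c2, c3 = c3)
  if (any(vals < 0 | vals > 1)) {
    stop("cutoffs must lie in [0, 1]", call. = FALSE)
  }
  if (c2 > c1) stop("c2 must not exceed c1", call. = FALSE)
  structure(list(c1 = c1, c2 = c2, c3 = c3, sens_floor = sens_floor),
            class = "cutoff_set")
}

#' @export
print.cutoff_set <- function(x, ...) {
  cat(sprintf(
    "Cutoffs: c1 = %.4g (positive), c2 = %.4g (suspicious), c3 = %.4g (adjudication); sensitivity floor %.0f%%\n",
    x$c1, x$c2, x$c3, 100 * x$sens_floor))
  invisible(x)
}

#' Select the referral (second-level) cutoff under a sensitivity floor
#'
#' Sweeps candidate values of `c2` (the unique fused scores below `c1`, plus
#' 0) and returns the largest one for which the overall sensitivity of the
#' full layered rule with cutoffs `(c1, c2, c3)` is at least `sens_floor` --
#' the largest feasible `c2` minimises enhanced-MRI referrals at the floor.
#' Overall sensitivity is non-increasing in `c2`, so the largest feasible
#' candidate is well defined.
#'
#' @param table a `"score_table"` with both classes present.
#' @param c1 first-level cutoff on the fused score.
#' @param c3 adjudication cutoff on the T1WIC score.
#' @param sens_floor required overall sensitivity (default 0.90).
#' @return a length-1 numeric with attributes `needed` and `attainable`:
#'   * the selected `c2` (`needed = TRUE`, `attainable = TRUE`) in the
#'     ordinary case;
#'   * `NA` with `needed = FALSE` when the first-level rule alone already
#'     meets the floor with an empty suspicious group (no second level
#'     needed);
#'   * `0` with `attainable = FALSE` (and a warning) when even `c2 = 0`
#'     cannot reach the floor given `c3`.
#' @export
select_secondary_cutoff <- function(table, c1, c3, sens_floor = 0.90) {
  table <- as_score_table(table)
  if (length(unique(table$label)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  fused <- fuse_scores(table$score_t1wi, table$score_t2wi)
  pos <- table$label == 1

  sens_at <- function(c2) {
    calls <- fused >= c1 |
      (fused >= c2 & fused < c1 & table$score_t1wic >= c3)
    sum(calls & pos) / sum(pos)
  }

  # first-level rule alone (empty suspicious group)
  if (sum(fused >= c1 & pos) / sum(pos) >= sens_floor) {
    return(structure(NA_real_, needed = FALSE, attainable = TRUE))
  }
  candidates <- sort(unique(c(0, fused[fused < c1])), decreasing = TRUE)
  for (c2 in candidates) {
    if (sens_at(c2) >= sens_floor) {
      return(structure(c2, needed = TRUE, attainable = TRUE))
    }
  }
  warning("sensitivity floor unattainable even at c2 = 0 given c3",
          call. = FALSE)
  structure(0, needed = TRUE, attainable = FALSE)
}
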