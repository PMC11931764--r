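#' Cost and examination-time parameters
#'
#' Per-examination unit costs and durations, the hypothetical cohort size and
#' the RMB/USD exchange rate. Default unit values are the whole-cohort totals
#' of the conventional (all-enhanced) and fused-model-only (all-unenhanced)
#' strategies divided by the 1,000-patient cohort — enhanced RMB 2,444 and
#' 0.2264 h, unenhanced RMB 2,246 and 0.1292 h per examination (2024
#' Guangzhou medical-insurance pricing) — since only cohort totals, not
#' per-examination prices, are published.
#'
#' @param cohort_n hypothetical cohort size (default 1000).
#' @param unit_cost_enhanced,unit_cost_unenhanced RMB per examination;
#'   enhanced must cost at least as much as unenhanced.
#' @param unit_time_enhanced,unit_time_unenhanced hours per examination.
#' @param fx_rate RMB per USD (default 7.17, the 2024 rate).
#' @return an object of class `"econ_params"`.
#' @export
econ_params <- function(cohort_n = 1000,
                        unit_cost_enhanced = 2444,
                        unit_cost_unenhanced = 2246,
                        unit_time_enhanced = 0.2264,
                        unit_time_unenhanced = 0.1292,
                        fx_rate = 7.17) {
  if (cohort_n < 1 || cohort_n != round(cohort_n)) {
    stop("cohort_n must be a positive integer", call. = FALSE)
  }
  if (!(unit_cost_enhanced >= unit_cost_unenhanced &&
        unit_cost_unenhanced > 0)) {
    stop("need unit_cost_enhanced >= unit_cost_unenhanced > 0", call. = FALSE)
  }
  if (unit_time_enhanced <= 0 || unit_time_unenhanced <= 0) {
    stop("unit times must be positive", call. = FALSE)
  }
  if (fx_rate <= 0) stop("fx_rate must be positive", call. = FALSE)
  structure(list(cohort_n = as.integer(cohort_n),
                 unit_cost_enhanced = unit_cost_enhanced,
                 unit_cost_unenhanced = unit_cost_unenhanced,
                 unit_time_enhanced = unit_time_enhanced,
                 unit_time_unenhanced = unit_time_unenhanced,
                 fx_rate = fx_rate),
            class = "econ_params")
}

# round to nearest integer, halves away from zero, then reconcile to a fixed
# total by largest remainder
largest_remainder <- function(x, total) {
  raw <- x * total / sum(x)
  base <- floor(raw)
  short <- as.integer(round(total - sum(base)))
  if (short > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

#' Project a strategy evaluation onto a hypothetical cohort
#'
#' Scales the per-group patient, true-case and detected counts of a test-set
#' evaluation to a hypothetical cohort of `cohort_n` patients (each count
#' scaled by `cohort_n / n` and rounded to the nearest integer). A
#' largest-remainder reconciliation forces the group patient counts to sum
#' exactly to `cohort_n`; detected <= true <= patients is enforced per group
#' after rounding.
#'
#' @param eval a `"strategy_evaluation"`.
#' @param cohort_n hypothetical cohort size (default 1000).
#' @return an object of class `"cohort_projection"`: a data frame with rows
#'   positive/suspicious/negative and columns `patients`, `true_cases`,
#'   `detected_true`, plus attributes `prevalence`, `cohort_n`,
#'   `strategy_name`.
#' @examples
#' # 200 of 433 test patients called positive, 166 truly recurrent
#' # -> 462 and 383 of 1,000
#' @export
project_cohort <- function(eval, cohort_n = 1000) {
  if (!inherits(eval, "strategy_evaluation")) {
    stop("eval must be a strategy_evaluation", call. = FALSE)
  }
  if (cohort_n < 1) stop("cohort_n must be >= 1", call. = FALSE)
  scale <- cohort_n / eval$n
  patients <- largest_remainder(eval$group_counts, cohort_n)
  true_cases <- as.integer(round_half_up(eval$group_true_counts * scale))
  detected <- as.integer(round_half_up(eval$group_detected_counts * scale))
  true_cases <- pmin(true_cases, patients)
  detected <- pmin(detected, true_cases)
  df <- data.frame(
    group = factor(c("positive", "suspicious", "negative"),
                   levels = c("positive", "suspicious", "negative")),
    patients = patients,
    true_cases = true_cases,
    detected_true = detected
  )
  structure(df,
            prevalence = sum(eval$group_true_counts) / eval$n,
            cohort_n = as.integer(cohort_n),
            strategy_name = eval$strategy_name,
            class = c("cohort_projection", "data.frame"))
}

#' Construct a cohort projection directly
#'
#' Builds the hypothetical-cohort group table from given counts, e.g. the
#' published 1,000-patient group sizes, rather than by scaling a test-set
#' evaluation with [project_cohort()].
#'
#' @param patients,true_cases,detected_true integer vectors of length 3
#'   (positive, suspicious, negative); `patients` must sum to `cohort_n` and
#'   `detected_true <= true_cases <= patients` per group.
#' @param cohort_n cohort size.
#' @param prevalence cohort prevalence.
#' @param strategy_name strategy the projection describes.
#' @return a `"cohort_projection"`.
#' @export
cohort_projection <- function(patients, true_cases, detected_true,
                              cohort_n = sum(patients), prevalence = NA_real_,
                              strategy_name = "darndest") {
  stopifnot(length(patients) == 3, length(true_cases) == 3,
            length(detected_true) == 3)
  if (sum(patients) != cohort_n) {
    stop("group patients must sum to cohort_n", call. = FALSE)
  }
  if (any(detected_true > true_cases) || any(true_cases > patients)) {
    stop("need detected_true <= true_cases <= patients in each group",
         call. = FALSE)
  }
  df <- data.frame(
    group = factor(c("positive", "suspicious", "negative"),
                   levels = c("positive", "suspicious", "negative")),
    patients = as.integer(patients),
    true_cases = as.integer(true_cases),
    detected_true = as.integer(detected_true)
  )
  structure(df, prevalence = prevalence, cohort_n = as.integer(cohort_n),
            strategy_name = strategy_name,
            class = c("cohort_projection", "data.frame"))
}

#' Cost of detecting one true-positive case in a group
#'
#' The benchmark is the conventional whole-cohort cost (every patient
#' scanned with contrast): `cohort_n * unit_cost_enhanced / detected_true`,
#' rounded to the nearest yuan. A group that detects nobody costs `Inf` per
#' detection.
#'
#' @param detected_true true-positive count detected in the group (>= 0).
#' @param params an [econ_params()].
#' @return cost in RMB per detected case (`Inf` if `detected_true` is 0).
#' @examples
#' cost_per_true_positive(383, econ_params()) # 6381
#' @export
cost_per_true_positive <- function(detected_true, params = econ_params()) {
  if (any(detected_true < 0)) stop("detected_true must be >= 0", call. = FALSE)
  total <- params$cohort_n * params$unit_cost_enhanced
  ifelse(detected_true == 0, Inf,
         round_half_up(total / detected_true))
}

#' Whole-cohort cost and time totals of a strategy
#'
#' Enhanced-scan counts per strategy: positive + suspicious patients
#' (layered rule), all patients (conventional or T1WIC-only), none
#' (fused-model-only). Cost in RMB (nearest yuan); time in hours to one
#' decimal.
#'
#' @param projection a `"cohort_projection"` (its group patient counts are
#'   used for the layered rule; other strategies need only `cohort_n`).
#' @param params an [econ_params()].
#' @param strategy strategy name.
#' @return `list(cost_rmb, time_hours, n_enhanced, n_unenhanced)`.
#' @export
strategy_totals <- function(projection, params = econ_params(),
                            strategy = c("darndest", "t1_t2_only",
                                         "t1wic_only", "conventional")) {
  strategy <- match.arg(strategy)
  cohort_n <- attr(projection, "cohort_n")
  if (is.null(cohort_n)) cohort_n <- params$cohort_n
  n_enh <- switch(strategy,
    darndest = sum(projection$patients[projection$group %in%
                                         c("positive", "suspicious")]),
    t1_t2_only = 0L,
    t1wic_only = cohort_n,
    conventional = cohort_n
  )
  n_unenh <- cohort_n - n_enh
  cost <- n_enh * params$unit_cost_enhanced +
    n_unenh * params$unit_cost_unenhanced
  time <- n_enh * params$unit_time_enhanced +
    n_unenh * params$unit_time_unenhanced
  list(cost_rmb = round_half_up(cost),
       time_hours = round_half_up(time, 1),
       n_enhanced = as.integer(n_enh),
       n_unenhanced = as.integer(n_unenh))
}

#' Convert RMB to US dollars
#'
#' @param amount_rmb amount in RMB.
#' @param fx_rate RMB per USD (default 7.17).
#' @return amount in USD, rounded to the nearest dollar.
#' @examples
#' convert_currency(2444000) # 340865
#' @export
convert_currency <- function(amount_rmb, fx_rate = 7.17) {
  if (fx_rate <= 0) stop("fx_rate must be positive", call. = FALSE)
  round_half_up(amount_rmb / fx_rate)
}

#' Cost ratio of two strategies, in percent
#'
#' @param numerator,denominator costs (same currency); denominator > 0.
#' @return `100 * numerator / denominator`, rounded to two decimals.
#' @examples
#' cost_ratio(2371293, 2444000) # 97.03
#' @export
cost_ratio <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("denominator must be positive", call. = FALSE)
  round_half_up(100 * numerator / denominator, 2)
}

#' Assemble the hypothetical-cohort economic report
#'
#' Combines per-group cost-per-detection, strategy cost/time totals (layered
#' rule, fused-model-only, conventional), dollar conversions and the layered
#' rule's cost relative to the two comparators.
#'
#' @param projection a `"cohort_projection"` of the layered-rule strategy.
#' @param params an [econ_params()].
#' @return an object of class `"econ_report"`.
#' @export
econ_report <- function(projection, params = econ_params()) {
  if (!inherits(projection, "cohort_projection")) {
    stop("projection must be a cohort_projection", call. = FALSE)
  }
  cpt <- cost_per_true_positive(projection$detected_true, params)
  totals <- lapply(stats::setNames(nm = c("darndest", "t1_t2_only",
                                          "conventional")),
                   function(s) strategy_totals(projection, params, s))
  for (s in names(totals)) {
    totals[[s]]$cost_usd <- convert_currency(totals[[s]]$cost_rmb,
                                             params$fx_rate)
  }
  structure(list(
    groups = data.frame(as.data.frame(projection), cost_per_tp = cpt),
    totals = totals,
    ratios = c(
      darndest_vs_t1_t2 = cost_ratio(totals$darndest$cost_rmb,
                                     totals$t1_t2_only$cost_rmb),
      darndest_vs_conventional = cost_ratio(totals$darndest$cost_rmb,
                                            totals$conventional$cost_rmb)
    ),
    prevalence = attr(projection, "prevalence"),
    params = params
  ), class = "econ_report")
}

#' @export
print.econ_report <- function(x, ...) {
  cat(sprintf("Hypothetical cohort of %d patients (prevalence %.1f%%)\n",
              x$params$cohort_n, 100 * x$prevalence))
  g <- x$groups
  for (i in seq_len(nrow(g))) {
    cat(sprintf("  %-10s %4d patients, %3d true, %3d detected, RMB %s per detection\n",
                as.character(g$group[i]), g$patients[i], g$true_cases[i],
                g$detected_true[i],
                if (is.finite(g$cost_per_tp[i]))
                  format(g$cost_per_tp[i], big.mark = ",") else "infinity"))
  }
  for (s in names(x$totals)) {
    t <- x$totals[[s]]
    cat(sprintf("  %-13s total RMB %s ($%s), %.1f h (%d enhanced scans)\n",
                s, format(t$cost_rmb, big.mark = ","),
                format(t$cost_usd, big.mark = ","), t$time_hours,
                t$n_enhanced))
  }
  cat(sprintf("  layered rule cost = %.2f%% of fused-only, %.2f%% of conventional\n",
              x$ratios["darndest_vs_t1_t2"],
              x$ratios["darndest_vs_conventional"]))
  invisible(x)
}
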