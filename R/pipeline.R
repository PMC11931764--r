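#' Pipeline configuration
#'
#' Exactly one of `input` (path to a score CSV) or `synthetic` (a
#' [synthetic_config()]) must be given. Cutoff overrides left `NULL` are
#' calibrated on the data.
#'
#' @param input path to a score-table CSV, or `NULL`.
#' @param synthetic a [synthetic_config()], or `NULL`.
#' @param c1,c2,c3 optional cutoff overrides.
#' @param sens_floor sensitivity floor for the `c2` search.
#' @param econ an [econ_params()].
#' @param alpha paired-test significance threshold (default 0.05/3).
#' @param conf_level confidence level (default 0.95).
#' @param mcnemar_correction continuity correction flag.
#' @param out_dir output directory for the report bundle.
#' @param seed integer seed (used by the synthetic generator).
#' @return an object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input = NULL, synthetic = NULL,
                            c1 = NULL, c2 = NULL, c3 = NULL,
                            sens_floor = 0.90, econ = econ_params(),
                            alpha = 0.05 / 3, conf_level = 0.95,
                            mcnemar_correction = FALSE,
                            out_dir = "darndest_report", seed = 1L) {
  if (is.null(input) == is.null(synthetic)) {
    stop("exactly one of input / synthetic must be given", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (!is.null(synthetic)) {
    if (!inherits(synthetic, "synthetic_config")) {
      stop("synthetic must be a synthetic_config", call. = FALSE)
    }
    synthetic$seed <- as.integer(seed)
  }
  structure(list(input = input, synthetic = synthetic,
                 c1 = c1, c2 = c2, c3 = c3, sens_floor = sens_floor,
                 econ = econ, alpha = alpha, conf_level = conf_level,
                 mcnemar_correction = mcnemar_correction,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

# serialise config and hash it (djb2 over the deparsed form) so the run
# log records exactly which configuration produced the bundle
config_hash <- function(config) {
  core <- unclass(config)
  core$out_dir <- NULL # where the bundle lands is not part of the analysis
  txt <- paste(deparse(core, control = "all"), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 5381
  for (b in bytes) {
    h <- (h * 33 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE, null = "null")
  path
}

#' Run the full follow-up evaluation pipeline
#'
#' Chains simulate (or load) -> calibrate -> triage -> evaluate -> economics
#' into one reproducible report bundle written under `config$out_dir`:
#' the score table (if simulated), the cutoff set (JSON), the per-patient
#' triage table (CSV), one strategy-evaluation JSON per strategy, the paired
#' McNemar / DeLong comparison table (JSON), the economic report (JSON) and
#' a run log with the configuration hash and package version. The bundle is
#' a pure function of configuration and seed.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the fitted `"darndest"` object, the
#'   summary, the economic report and the written file paths.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop("config must be a pipeline_config", call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  table <- step("input", {
    if (!is.null(config$synthetic)) {
      tab <- generate_cohort(config$synthetic)
      paths$scores <- file.path(config$out_dir, "scores.csv")
      write_score_table(tab, paths$scores)
      tab
    } else {
      read_score_table(config$input)
    }
  })

  fit <- step("calibrate", darndest(
    table, c1 = config$c1, c2 = config$c2, c3 = config$c3,
    sens_floor = config$sens_floor, conf_level = config$conf_level,
    alpha = config$alpha, mcnemar_correction = config$mcnemar_correction))

  paths$cutoffs <- file.path(config$out_dir, "cutoffs.json")
  step("calibrate", write_json_report(unclass(fit$cutoffs), paths$cutoffs))

  paths$triage <- file.path(config$out_dir, "triage.csv")
  step("triage", utils::write.csv(
    as.data.frame(fit$outcome)[c("patient_id", "group", "mri_mode",
                                 "final_call")],
    paths$triage, row.names = FALSE, quote = FALSE))

  sm <- step("evaluate", summary(fit))
  for (s in c("t1_t2_only", "t1wic_only", "darndest")) {
    ev <- fit$evaluations[[s]]
    paths[[paste0("evaluation_", s)]] <-
      file.path(config$out_dir, paste0("evaluation_", s, ".json"))
    step("evaluate", write_json_report(list(
      strategy = ev$strategy_name,
      confusion = unclass(ev$confusion),
      metrics = lapply(ev$summary[c("sensitivity", "specificity", "accuracy",
                                    "ppv", "npv")],
                       function(v) round_half_up(v, 2)),
      group_counts = as.list(ev$group_counts),
      group_true_counts = as.list(ev$group_true_counts),
      group_detected_counts = as.list(ev$group_detected_counts),
      n_enhanced = ev$n_enhanced
    ), paths[[paste0("evaluation_", s)]]))
  }

  paths$comparisons <- file.path(config$out_dir, "comparisons.json")
  step("evaluate", write_json_report(list(
    mcnemar = lapply(sm$mcnemar, function(t)
      list(statistic = t$statistic, p_value = t$p_value,
           significant = t$significant)),
    delong = lapply(sm$delong, function(t)
      list(auc_a = t$auc_a, auc_b = t$auc_b, statistic = t$statistic,
           p_value = t$p_value, significant = t$significant)),
    auc = lapply(sm$roc, function(r)
      list(auc = r$auc, ci_low = r$auc_ci_low, ci_high = r$auc_ci_high)),
    alpha = config$alpha
  ), paths$comparisons))

  econ <- step("economics", {
    proj <- project_cohort(fit$evaluations$darndest, config$econ$cohort_n)
    econ_report(proj, config$econ)
  })
  paths$econ <- file.path(config$out_dir, "econ.json")
  step("economics", write_json_report(list(
    groups = econ$groups,
    totals = econ$totals,
    ratios = as.list(econ$ratios),
    prevalence = econ$prevalence
  ), paths$econ))

  paths$run_log <- file.path(config$out_dir, "run_log.json")
  write_json_report(list(
    package = "darndest",
    version = as.character(utils::packageVersion("darndest")),
    seed = config$seed,
    config_hash = config_hash(config),
    stages = c("input", "calibrate", "triage", "evaluate", "economics")
  ), paths$run_log)

  invisible(list(fit = fit, summary = sm, econ = econ, paths = paths))
}
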