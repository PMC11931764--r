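#' Configuration for the synthetic score-cohort generator
#'
#' The generator emulates the statistical structure the analysis assumes:
#' two-class trivariate scores with a target prevalence, per-model
#' discrimination (AUC) and positive inter-score correlation. Defaults match
#' the internal test-cohort conditions the pipeline was designed around:
#' 433 patients at prevalence 197/433 and per-sequence AUCs of about 0.91.
#'
#' @param n cohort size (>= 2).
#' @param prevalence recurrence prevalence in (0, 1).
#' @param auc_targets named numeric of length 3, target AUC of each score
#'   against the label, each in (0.5, 1) exclusive.
#' @param correlation pairwise within-class latent correlation in \[0, 1),
#'   induced by a single shared latent factor.
#' @param seed integer RNG seed; identical seeds give identical cohorts.
#' @return an object of class `"synthetic_config"`.
#' @seealso [generate_cohort()]
#' @export
synthetic_config <- function(n = 433, prevalence = 197 / 433,
                             auc_targets = c(t1wi = 0.9098, t2wi = 0.9145,
                                             t1wic = 0.9124),
                             correlation = 0.5, seed = 1L) {
  if (length(n) != 1 || n < 2 || n != round(n)) {
    stop("n must be a single integer >= 2", call. = FALSE)
  }
  if (prevalence <= 0 || prevalence >= 1) {
    stop("prevalence must lie in (0, 1)", call. = FALSE)
  }
  if (n * prevalence < 1 || n * (1 - prevalence) < 1) {
    stop("n and prevalence must give at least one expected member per class",
         call. = FALSE)
  }
  if (length(auc_targets) != 3 || any(auc_targets <= 0.5) ||
      any(auc_targets >= 1)) {
    stop("auc_targets must be three values in (0.5, 1) exclusive",
         call. = FALSE)
  }
  if (is.null(names(auc_targets))) {
    names(auc_targets) <- c("t1wi", "t2wi", "t1wic")
  }
  if (correlation < 0 || correlation >= 1) {
    stop("correlation must lie in [0, 1)", call. = FALSE)
  }
  structure(list(n = as.integer(n), prevalence = prevalence,
                 auc_targets = auc_targets, correlation = correlation,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Binormal class separation for a target AUC
#'
#' Under the equal-variance binormal model (class-0 latents N(0,1), class-1
#' latents N(delta,1)) the AUC is `pnorm(delta / sqrt(2))`; this returns the
#' separation `delta` giving a requested AUC.
#'
#' @param auc target AUC in (0.5, 1) exclusive (vectorised).
#' @return the latent mean shift `delta = sqrt(2) * qnorm(auc)`.
#' @examples
#' auc_to_separation(0.9107) # about 1.90
#' @export
auc_to_separation <- function(auc) {
  if (any(auc <= 0.5) || any(auc >= 1)) {
    stop("auc must lie strictly inside (0.5, 1)", call. = FALSE)
  }
  sqrt(2) * stats::qnorm(auc)
}

#' Generate a synthetic score cohort
#'
#' Labels are Bernoulli(prevalence). For each patient a shared latent factor
#' plus model-specific noise yields three latent values with pairwise
#' within-class correlation `correlation`; class-1 latents are shifted by
#' each model's binormal separation (see [auc_to_separation()]); scores are
#' the logistic transform of the latents, so they lie strictly inside (0, 1)
#' and, the transform being rank-preserving, each score's AUC against the
#' label equals its target in expectation.
#'
#' A label draw that produces a single-class cohort is redrawn up to 100
#' times, after which the function errors rather than return a degenerate
#' cohort.
#'
#' @param config a [synthetic_config()].
#' @return a `"score_table"` with `config$n` rows, cohort tag "synthetic".
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    stop("config must be a synthetic_config", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  n <- config$n
  labels <- stats::rbinom(n, 1L, config$prevalence)
  tries <- 0L
  while (length(unique(labels)) < 2L) {
    tries <- tries + 1L
    if (tries > 100L) {
      stop("failed to draw a two-class cohort in 100 attempts; ",
           "increase n or move prevalence away from 0/1", call. = FALSE)
    }
    labels <- stats::rbinom(n, 1L, config$prevalence)
  }

  delta <- auc_to_separation(config$auc_targets)
  lambda <- sqrt(config$correlation)
  shared <- stats::rnorm(n)
  scores <- vapply(seq_len(3), function(m) {
    z <- lambda * shared + sqrt(1 - config$correlation) * stats::rnorm(n) +
      labels * delta[m]
    stats::plogis(z)
  }, numeric(n))

  score_table(
    patient_id = sprintf("SYN%05d", seq_len(n)),
    label = labels,
    score_t1wi = scores[, 1],
    score_t2wi = scores[, 2],
    score_t1wic = scores[, 3],
    cohort_tag = "synthetic"
  )
}
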