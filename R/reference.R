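#' Published reference confusion counts for the two test cohorts
#'
#' The per-model (and per-radiologist) TP/FN/FP/TN counts reported for the
#' internal (197 recurrent of 433) and external (93 of 202) test cohorts,
#' plus the counts of the layered rule itself, reconstructed from its
#' reported sensitivity and specificity. These printed counts are the inputs
#' from which every reported diagnostic percentage is reproducible; the test
#' suite and the acceptance script recompute the reported metrics from them.
#'
#' @return a data frame with columns `cohort`, `reader`, `tp`, `fn`, `fp`,
#'   `tn`.
#' @export
reference_test_counts <- function() {
  df <- rbind(
    data.frame(cohort = "internal",
               reader = c("t1wic", "t1wi", "t2wi", "t1_t2",
                          "doctor_senior", "doctor_junior", "darndest"),
               tp = c(166, 168, 164, 166, 154, 166, 178),
               fn = c(31, 29, 33, 31, 43, 31, 19),
               fp = c(35, 40, 40, 34, 13, 41, 42),
               tn = c(201, 196, 196, 202, 223, 195, 194)),
    data.frame(cohort = "external",
               reader = c("t1wic", "t1wi", "t2wi", "t1_t2",
                          "doctor_senior", "doctor_junior", "darndest"),
               tp = c(78, 75, 76, 79, 77, 72, 84),
               fn = c(15, 18, 17, 14, 16, 21, 9),
               fp = c(19, 19, 16, 18, 3, 4, 19),
               tn = c(90, 90, 93, 91, 106, 105, 90))
  )
  df
}

#' Published hypothetical-cohort inputs of the economic analysis
#'
#' Group sizes, true-case counts and detected counts of the 1,000-patient
#' hypothetical cohorts (internal and external pricing of the layered rule),
#' the published first-level cutoffs, the test-set counts behind the cohort
#' scaling, and the published whole-cohort cost totals. The "detected" count
#' of the negative group refers to cases confirmed only at later follow-up;
#' at the index examination the rule calls the negative group recurrence-free.
#'
#' @return a nested list with `internal`, `external`, `cutoffs` and `totals`
#'   components.
#' @export
reference_econ_inputs <- function() {
  list(
    internal = list(
      test_n = 433, test_true = 197,
      t1_t2_positive_calls = 200, t1_t2_true_positives = 166,
      groups = c(positive = 462, suspicious = 171, negative = 367),
      true_cases = c(positive = 383, suspicious = 62, negative = 9),
      detected = c(positive = 383, suspicious = 28, negative = 5),
      n_enhanced = 633, n_unenhanced = 367
    ),
    external = list(
      test_n = 202, test_true = 93,
      groups = c(positive = 480, suspicious = 89, negative = 431),
      true_cases = c(positive = 391, suspicious = 35, negative = 35),
      detected = c(positive = 391, suspicious = 25, negative = 5),
      n_enhanced = 569, n_unenhanced = 431
    ),
    cutoffs = list(internal = c(c1 = 0.490, c2 = 0.197),
                   external = c(c1 = 0.460, c2 = 0.282)),
    totals = list(conventional_rmb = 2444000, t1_t2_rmb = 2246000,
                  darndest_internal_rmb = 2371293,
                  darndest_external_rmb = 2358723)
  )
}
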