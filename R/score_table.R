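#' Construct a per-patient score table
#'
#' The score table is the universal input of every pipeline stage: one row per
#' patient with a binary recurrence label and the three per-sequence model
#' scores (T1-weighted, T2-weighted, post-contrast T1-weighted).
#'
#' @param patient_id character vector of unique patient identifiers.
#' @param label integer vector, 1 = local recurrence, 0 = recurrence-free.
#' @param score_t1wi,score_t2wi,score_t1wic numeric model scores in \[0, 1\].
#' @param cohort_tag free-text tag for the cohort (e.g. "internal").
#' @return A `data.frame` of class `"score_table"` with a `cohort_tag`
#'   attribute; row order is preserved by all readers and writers.
#' @examples
#' score_table(c("P1", "P2"), c(1, 0), c(0.9, 0.2), c(0.8, 0.3), c(0.95, 0.1))
#' @export
score_table <- function(patient_id, label, score_t1wi, score_t2wi,
                        score_t1wic, cohort_tag = "") {
  df <- data.frame(
    patient_id = as.character(patient_id),
    label = as.integer(label),
    score_t1wi = as.numeric(score_t1wi),
    score_t2wi = as.numeric(score_t2wi),
    score_t1wic = as.numeric(score_t1wic),
    stringsAsFactors = FALSE
  )
  as_score_table(df, cohort_tag = cohort_tag)
}

#' Coerce and validate a data frame as a score table
#'
#' @param x a data frame with columns `patient_id`, `label`, `score_t1wi`,
#'   `score_t2wi`, `score_t1wic`.
#' @param cohort_tag cohort tag; defaults to the existing attribute or "".
#' @return the validated `"score_table"`.
#' @export
as_score_table <- function(x, cohort_tag = NULL) {
  required <- c("patient_id", "label", "score_t1wi", "score_t2wi", "score_t1wic")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("score table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- as.data.frame(x)[required]
  x$patient_id <- as.character(x$patient_id)
  if (anyNA(x)) {
    bad <- x$patient_id[!stats::complete.cases(x)]
    stop("missing values in score table for patient(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!all(x$label %in% c(0, 1))) {
    bad <- x$patient_id[!x$label %in% c(0, 1)]
    stop("label must be 0 or 1; offending patient(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  x$label <- as.integer(x$label)
  for (col in c("score_t1wi", "score_t2wi", "score_t1wic")) {
    s <- x[[col]]
    if (!is.numeric(s)) stop("column ", col, " must be numeric", call. = FALSE)
    out <- s < 0 | s > 1
    if (any(out)) {
      stop(col, " outside [0, 1] for patient(s): ",
           paste(x$patient_id[out], collapse = ", "), call. = FALSE)
    }
  }
  dup <- duplicated(x$patient_id)
  if (any(dup)) {
    stop("duplicate patient_id: ",
         paste(unique(x$patient_id[dup]), collapse = ", "), call. = FALSE)
  }
  if (nrow(x) < 1) stop("score table must be non-empty", call. = FALSE)
  if (is.null(cohort_tag)) {
    cohort_tag <- attr(x, "cohort_tag")
    if (is.null(cohort_tag)) cohort_tag <- ""
  }
  rownames(x) <- NULL
  structure(x, cohort_tag = as.character(cohort_tag)[1],
            class = c("score_table", "data.frame"))
}

#' Read a score table from delimited text
#'
#' Expects a header row naming the five required columns
#' `patient_id,label,score_t1wi,score_t2wi,score_t1wic`. Labels are normally
#' coded 1/0; `label_map` accepts string-coded labels instead (e.g.
#' `c(recurrent = 1, free = 0)`).
#'
#' @param path path to the file.
#' @param sep field separator (default comma).
#' @param label_map optional named vector mapping string labels to 1/0.
#' @param cohort_tag cohort tag attached to the result.
#' @return a validated `"score_table"`, row order as in the file.
#' @seealso [write_score_table()]
#' @export
read_score_table <- function(path, sep = ",", label_map = NULL,
                             cohort_tag = "") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = TRUE,
                          stringsAsFactors = FALSE)
  required <- c("patient_id", "label", "score_t1wi", "score_t2wi", "score_t1wic")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("score file ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!is.null(label_map)) {
    mapped <- unname(label_map[df$label])
    if (anyNA(mapped)) {
      stop("label values not covered by label_map: ",
           paste(unique(df$label[is.na(mapped)]), collapse = ", "),
           call. = FALSE)
    }
    df$label <- mapped
  }
  df$label <- as.numeric(df$label)
  for (col in c("score_t1wi", "score_t2wi", "score_t1wic")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  as_score_table(df, cohort_tag = cohort_tag)
}

#' Write a score table to delimited text
#'
#' Scores are written with enough significant digits (17) that reading the
#' file back reproduces every field exactly.
#'
#' @param x a `"score_table"`.
#' @param path output path.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_score_table <- function(x, path, sep = ",") {
  x <- as_score_table(x)
  out <- data.frame(
    patient_id = x$patient_id,
    label = as.character(x$label),
    score_t1wi = formatC(x$score_t1wi, digits = 17, format = "g"),
    score_t2wi = formatC(x$score_t2wi, digits = 17, format = "g"),
    score_t1wic = formatC(x$score_t1wic, digits = 17, format = "g"),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.score_table <- function(x, ...) {
  tag <- attr(x, "cohort_tag")
  cat(sprintf("Score table: %d patients (%d recurrent, %d recurrence-free)%s\n",
              nrow(x), sum(x$label == 1), sum(x$label == 0),
              if (nzchar(tag)) paste0(", cohort '", tag, "'") else ""))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Construct a 2x2 confusion matrix
#'
#' @param tp,fn,fp,tn non-negative integer counts (true/false
#'   positives/negatives).
#' @return an object of class `"confusion_matrix"`.
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) < 1) stop("confusion matrix must summarise at least one case",
                            call. = FALSE)
  structure(as.list(stats::setNames(as.integer(counts), names(counts))),
            class = "confusion_matrix")
}

#' Tally a confusion matrix from labels and binary calls
#'
#' @param labels binary ground-truth vector (1 = recurrence).
#' @param calls binary predicted calls, same length.
#' @return a `"confusion_matrix"`; counts sum to `length(labels)`.
#' @examples
#' confusion_from_calls(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
confusion_from_calls <- function(labels, calls) {
  if (length(labels) != length(calls)) {
    stop("labels and calls must have equal length", call. = FALSE)
  }
  if (length(labels) < 1) stop("need at least one case", call. = FALSE)
  if (!all(labels %in% c(0, 1)) || !all(calls %in% c(0, 1))) {
    stop("labels and calls must be binary (0/1)", call. = FALSE)
  }
  confusion_matrix(
    tp = sum(labels == 1 & calls == 1),
    fn = sum(labels == 1 & calls == 0),
    fp = sum(labels == 0 & calls == 1),
    tn = sum(labels == 0 & calls == 0)
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(truth = c("recurrent", "free"),
                              call = c("positive", "negative")))
  print(m)
  invisible(x)
}
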