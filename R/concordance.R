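# Variable-level concordance between each review and the reference standard.
#
# Each study unit contributes four variables per outcome (events and total
# in each of the two arms). A variable the review reports is compared with
# the reference value; the error/selection classification itself is an
# input (the annotation layer), because deciding whether a discrepant value
# is a transcription error or a defensible alternative reading of the
# primary publication is a human judgement, not a computation.

#' Compare one review extraction against the reference extraction
#'
#' Produces one comparison row per variable. `differs` is computed from the
#' stored values; the taxonomy label is taken from the matching annotation
#' when one exists, and otherwise defaults to `identical` for equal values
#' and `error` for unequal ones. When the review cell is not reported the
#' label is `not_reported`. When the review reports but the reference does
#' not, the value cannot be compared in-corpus; an annotation (normally
#' adjudicated against the primary publications) supplies the label, and an
#' unannotated variable defaults to `error` with a warning.
#'
#' @param review_rec,reference_rec one-row data.frames in the extraction
#'   layout (same `study_unit_id` and `outcome_id`).
#' @param annotations annotation table (possibly empty) in the
#'   [audit_corpus()] annotation layout.
#' @return data.frame with one row per variable: `variable`,
#'   `review_value`, `reference_value`, `differs`, `label`, `adjudicated`.
#' @export
compare_study <- function(review_rec, reference_rec, annotations = NULL) {
  review_rec <- as.data.frame(review_rec)
  if (nrow(review_rec) != 1L)
    stop("review_rec must be a single extraction row", call. = FALSE)
  if (is.null(annotations)) annotations <- empty_annotations()
  ref_nr <- is.null(reference_rec) || all(is.na(unlist(
    as.data.frame(reference_rec)[1, COUNT_COLS])))
  if (!is.null(reference_rec)) {
    reference_rec <- as.data.frame(reference_rec)
    if (nrow(reference_rec) != 1L)
      stop("reference_rec must be a single extraction row", call. = FALSE)
    if (review_rec$study_unit_id != reference_rec$study_unit_id ||
        review_rec$outcome_id != reference_rec$outcome_id)
      stop("review and reference records are for different study units or outcomes",
           call. = FALSE)
  }

  out <- data.frame(variable = VARIABLES,
                    review_value = NA_integer_,
                    reference_value = NA_integer_,
                    differs = FALSE,
                    label = NA_character_,
                    adjudicated = FALSE,
                    stringsAsFactors = FALSE)
  review_nr <- review_rec$status == "not_reported"
  for (k in seq_along(VARIABLES)) {
    v <- VARIABLES[k]
    rv <- if (review_nr) NA_integer_ else as.integer(review_rec[[v]])
    fv <- if (ref_nr) NA_integer_ else as.integer(reference_rec[[v]])
    out$review_value[k] <- rv
    out$reference_value[k] <- fv
    ann <- annotations[annotations$review_id == review_rec$review_id &
                         annotations$study_unit_id == review_rec$study_unit_id &
                         annotations$outcome_id == review_rec$outcome_id &
                         annotations$variable == v, , drop = FALSE]
    has_ann <- nrow(ann) == 1L
    if (has_ann) out$adjudicated[k] <- ann$adjudicated

    if (review_nr) {
      out$differs[k] <- FALSE
      out$label[k] <- "not_reported"
    } else if (ref_nr) {
      out$differs[k] <- TRUE
      if (has_ann) {
        out$label[k] <- ann$label
      } else {
        warning(sprintf(
          "%s/%s/%s/%s: review reports a value but the reference does not; no annotation, defaulting to 'error'",
          review_rec$review_id, review_rec$study_unit_id,
          review_rec$outcome_id, v), call. = FALSE)
        out$label[k] <- "error"
      }
    } else {
      out$differs[k] <- rv != fv
      out$label[k] <- if (has_ann) ann$label
        else if (rv != fv) "error" else "identical"
    }
  }
  out
}

# Pick the timepoint at which a review analysed one study unit for one
# outcome. Reviews reporting a single timepointed (or unspecified) row are
# compared at that row; a review reporting several timepoints is compared
# at the earliest (one_year before thirteen_year). A fixed-timepoint policy
# restricts the analysed set to units reported at that timepoint (rows with
# an unspecified timepoint always qualify).
analysed_row <- function(corpus, review_id, unit_id, outcome_id,
                         timepoint_policy) {
  e <- corpus$extractions
  rows <- e[e$review_id == review_id & e$study_unit_id == unit_id &
              e$outcome_id == outcome_id & e$status == "reported", ,
            drop = FALSE]
  if (nrow(rows) == 0L) return(NULL)
  if (timepoint_policy != "as_analysed") {
    rows <- rows[rows$timepoint %in% c(timepoint_policy, "unspecified"), ,
                 drop = FALSE]
    if (nrow(rows) == 0L) return(NULL)
  }
  rows <- rows[order(match(rows$timepoint, TIMEPOINTS)), , drop = FALSE]
  rows[1, , drop = FALSE]
}

reference_counterpart <- function(corpus, review_row) {
  ref <- find_extraction(corpus, corpus$reference_review_id,
                         review_row$study_unit_id, review_row$outcome_id,
                         timepoint = review_row$timepoint)
  if (is.null(ref) && review_row$timepoint != "unspecified")
    ref <- find_extraction(corpus, corpus$reference_review_id,
                           review_row$study_unit_id, review_row$outcome_id,
                           timepoint = "unspecified")
  ref
}

#' Difference rates of one review against the reference, for one outcome
#'
#' Counts, over the study units the review analysed (reported data for),
#' how many of the 4-per-unit variables are classified as extraction errors
#' and as selection differences, and expresses each as a round-half-up
#' integer percentage of all compared variables. Units the review did not
#' report do not enter the denominator.
#'
#' @param corpus an [audit_corpus()].
#' @param review_id review to audit (not the reference).
#' @param outcome_id outcome to audit.
#' @param timepoint_policy `"as_analysed"` (default) compares each study
#'   unit at the timepoint the review analysed; `"one_year"` or
#'   `"thirteen_year"` restrict the analysed set to that timepoint.
#' @return A one-row data.frame of class `difference_rate_summary`:
#'   `review_id`, `outcome_id`, `n_units_analysed`, `n_variables`,
#'   `n_identical`, `n_error`, `n_selection`, `n_not_reported`,
#'   `pct_error`, `pct_selection`.
#' @export
audit_outcome <- function(corpus, review_id, outcome_id,
                          timepoint_policy = c("as_analysed", "one_year",
                                               "thirteen_year")) {
  stopifnot(inherits(corpus, "audit_corpus"))
  timepoint_policy <- match.arg(timepoint_policy)
  if (review_id == corpus$reference_review_id)
    stop("review_id must differ from the reference review", call. = FALSE)
  if (!review_id %in% corpus$reviews)
    stop("unknown review: ", review_id, call. = FALSE)
  if (!outcome_id %in% OUTCOMES)
    stop("unknown outcome: ", outcome_id, call. = FALSE)

  counts <- c(identical = 0L, error = 0L, selection = 0L, not_reported = 0L)
  n_units <- 0L
  for (unit in corpus$study_units$unit_id) {
    row <- analysed_row(corpus, review_id, unit, outcome_id, timepoint_policy)
    if (is.null(row)) next
    n_units <- n_units + 1L
    ref <- reference_counterpart(corpus, row)
    cmp <- compare_study(row, ref, corpus$annotations)
    tab <- table(factor(cmp$label, levels = LABELS))
    counts <- counts + as.integer(tab)
  }
  n_vars <- 4L * n_units
  out <- data.frame(review_id = review_id, outcome_id = outcome_id,
                    n_units_analysed = n_units, n_variables = n_vars,
                    n_identical = counts[["identical"]],
                    n_error = counts[["error"]],
                    n_selection = counts[["selection"]],
                    n_not_reported = counts[["not_reported"]],
                    pct_error = if (n_vars) round_half_up(100 * counts[["error"]] / n_vars) else 0,
                    pct_selection = if (n_vars) round_half_up(100 * counts[["selection"]] / n_vars) else 0,
                    stringsAsFactors = FALSE)
  class(out) <- c("difference_rate_summary", class(out))
  out
}

#' Difference-rate table for every non-reference review and outcome
#'
#' @inheritParams audit_outcome
#' @return data.frame of [audit_outcome()] rows, one per review x outcome.
#' @export
difference_rate_table <- function(corpus, timepoint_policy = "as_analysed") {
  stopifnot(inherits(corpus, "audit_corpus"))
  reviews <- setdiff(corpus$reviews, corpus$reference_review_id)
  out <- do.call(rbind, lapply(reviews, function(r)
    do.call(rbind, lapply(OUTCOMES, function(o)
      audit_outcome(corpus, r, o, timepoint_policy)))))
  rownames(out) <- NULL
  out
}

#' Check that annotation labels agree with the stored values
#'
#' A label is compatible with the computed comparison when: `identical`
#' annotates a variable whose value equals the reference (or an adjudicated
#' variable); `error` / `selection` annotate a variable that differs from
#' the reference, has a not-reported reference cell (adjudication against
#' the primary publications required), or is explicitly adjudicated; and
#' `not_reported` annotates a cell the review did not report. Incompatible
#' annotations are reported, not raised.
#'
#' @param corpus an [audit_corpus()].
#' @return data.frame of inconsistencies (zero rows when the annotation
#'   layer is coherent): the annotation key columns plus `problem`.
#' @export
check_annotation_consistency <- function(corpus) {
  stopifnot(inherits(corpus, "audit_corpus"))
  ann <- corpus$annotations
  problems <- character(nrow(ann))
  for (i in seq_len(nrow(ann))) {
    a <- ann[i, ]
    row <- analysed_row(corpus, a$review_id, a$study_unit_id, a$outcome_id,
                        "as_analysed")
    if (is.null(row)) {
      # review reported nothing for this unit/outcome
      if (a$label != "not_reported")
        problems[i] <- "review cell not reported but label is not 'not_reported'"
      next
    }
    ref <- reference_counterpart(corpus, row)
    ref_nr <- is.null(ref) || ref$status == "not_reported"
    rv <- as.integer(row[[a$variable]])
    fv <- if (ref_nr) NA_integer_ else as.integer(ref[[a$variable]])
    if (a$label == "not_reported") {
      problems[i] <- "review reports a value but label is 'not_reported'"
    } else if (ref_nr) {
      if (!a$adjudicated)
        problems[i] <- "reference cell not reported; label requires adjudication against the primary publication"
    } else if (a$label == "identical") {
      if (rv != fv && !a$adjudicated)
        problems[i] <- "label 'identical' on values that differ"
    } else { # error / selection
      if (rv == fv && !a$adjudicated)
        problems[i] <- "label implies a difference but values are equal and not adjudicated"
    }
  }
  bad <- problems != ""
  out <- cbind(ann[bad, c("review_id", "study_unit_id", "outcome_id",
                          "variable", "label"), drop = FALSE],
               problem = problems[bad])
  rownames(out) <- NULL
  out
}

# Round half away from zero (so 12.5 -> 13), matching how the audit
# percentages are reported; base round() would give banker's rounding.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
print.difference_rate_summary <- function(x, ...) {
  cat(sprintf(
    "%s vs reference, %s: %d units (%d variables); errors %d (%d%%), selection %d (%d%%)\n",
    x$review_id, x$outcome_id, x$n_units_analysed, x$n_variables,
    x$n_error, x$pct_error, x$n_selection, x$pct_selection))
  invisible(x)
}
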