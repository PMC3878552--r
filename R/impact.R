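# Cross-review sensitivity: do extraction differences move the pooled
# estimate, and do they change the qualitative conclusion?

#' Compare two pooled results for the same outcome and timepoint
#'
#' Significance is judged by the 95% confidence interval excluding 1
#' rather than by a rounded p-value. A "flip" is a pair in which exactly
#' one of the two pooled intervals excludes 1.
#'
#' @param a,b `pooled_result` objects carrying `outcome_id` / `timepoint`
#'   attributes (as returned by [pooled_from_corpus()]).
#' @return A one-row data.frame of class `impact_comparison`:
#'   `outcome_id`, `timepoint`, `review_a`, `review_b`, `rr_a`, `rr_b`,
#'   `log_rr_difference`, `ratio_of_rrs`, `significant_a`,
#'   `significant_b`, `flip`.
#' @export
compare_pooled <- function(a, b) {
  stopifnot(inherits(a, "pooled_result"), inherits(b, "pooled_result"))
  oa <- attr(a, "outcome_id"); ob <- attr(b, "outcome_id")
  ta <- attr(a, "timepoint"); tb <- attr(b, "timepoint")
  if (!is.null(oa) && !is.null(ob) && (oa != ob || !identical(ta, tb)))
    stop("pooled results are for different outcomes or timepoints",
         call. = FALSE)
  sig <- function(x) x$ci_low > 1 || x$ci_high < 1
  out <- data.frame(
    outcome_id = if (is.null(oa)) NA_character_ else oa,
    timepoint = if (is.null(ta)) NA_character_ else ta,
    review_a = attr(a, "review_id") %||% NA_character_,
    review_b = attr(b, "review_id") %||% NA_character_,
    rr_a = a$rr, rr_b = b$rr,
    log_rr_difference = abs(a$log_rr - b$log_rr),
    ratio_of_rrs = a$rr / b$rr,
    significant_a = sig(a), significant_b = sig(b),
    flip = sig(a) != sig(b),
    stringsAsFactors = FALSE)
  class(out) <- c("impact_comparison", class(out))
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Impact report: reference review versus every other review
#'
#' Pools every review x outcome x timepoint cell with data and compares
#' each non-reference review's pooled result against the reference at the
#' matching outcome and timepoint; pairs where either side lacks data are
#' skipped. The pooled grid itself is attached as attribute `pooled`.
#'
#' @inheritParams meta_table
#' @return data.frame of [compare_pooled()] rows (zero rows for a
#'   single-review corpus), with the [meta_table()] grid as attribute
#'   `pooled`.
#' @export
impact_report <- function(corpus, exclusions = NULL, estimator = "dl",
                          correction = "half") {
  stopifnot(inherits(corpus, "audit_corpus"))
  grid <- meta_table(corpus, exclusions = exclusions, estimator = estimator,
                     correction = correction)
  ref <- corpus$reference_review_id
  out <- list()
  if (!is.null(grid)) {
    ref_cells <- grid[grid$review_id == ref, , drop = FALSE]
    for (i in seq_len(nrow(ref_cells))) {
      rc <- ref_cells[i, ]
      others <- grid[grid$review_id != ref &
                       grid$outcome_id == rc$outcome_id &
                       grid$timepoint == rc$timepoint, , drop = FALSE]
      for (j in seq_len(nrow(others))) {
        oc <- others[j, ]
        a <- pooled_from_corpus(corpus, ref, rc$outcome_id, rc$timepoint,
                                exclude_units = cell_exclusions(exclusions, ref, rc$outcome_id, rc$timepoint),
                                estimator = estimator, correction = correction)
        b <- pooled_from_corpus(corpus, oc$review_id, oc$outcome_id,
                                oc$timepoint,
                                exclude_units = cell_exclusions(exclusions, oc$review_id, oc$outcome_id, oc$timepoint),
                                estimator = estimator, correction = correction)
        out[[length(out) + 1L]] <- compare_pooled(a, b)
      }
    }
  }
  out <- if (length(out)) do.call(rbind, out) else {
    x <- data.frame(outcome_id = character(), timepoint = character(),
                    review_a = character(), review_b = character(),
                    rr_a = numeric(), rr_b = numeric(),
                    log_rr_difference = numeric(), ratio_of_rrs = numeric(),
                    significant_a = logical(), significant_b = logical(),
                    flip = logical(), stringsAsFactors = FALSE)
    class(x) <- c("impact_comparison", class(x))
    x
  }
  rownames(out) <- NULL
  attr(out, "pooled") <- grid
  out
}

cell_exclusions <- function(exclusions, review, outcome, tp) {
  if (is.null(exclusions)) return(character())
  m <- exclusions$review_id == review & exclusions$outcome_id == outcome &
    exclusions$timepoint == tp
  exclusions$study_unit_id[m]
}

#' Render an impact report as markdown
#'
#' @param report result of [impact_report()].
#' @return character vector of markdown lines.
#' @export
render_impact_markdown <- function(report) {
  lines <- c("| Outcome | Timepoint | Reference | Review | RR (ref) | RR (review) | |log RR diff| | Flip |",
             "|---|---|---|---|---|---|---|---|")
  for (i in seq_len(nrow(report))) {
    r <- report[i, ]
    lines <- c(lines, sprintf(
      "| %s | %s | %s | %s | %.2f | %.2f | %.3f | %s |",
      r$outcome_id, r$timepoint, r$review_a, r$review_b, r$rr_a, r$rr_b,
      r$log_rr_difference, if (r$flip) "YES" else "no"))
  }
  n_flip <- sum(report$flip)
  c(lines, "", sprintf(
    "%d of %d reference-vs-review comparisons change significance.",
    n_flip, nrow(report)))
}
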