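# Synthetic multi-review extraction corpora with known ground truth.
#
# A reference review extracts the (correct) event data of n simulated
# two-arm trials; each further review is a perturbed copy in which typed
# extraction errors (denominator transposition, numerator recalculation
# from rounded percentages) and typed selection differences (alternative
# comparator arm, alternative follow-up timepoint, different
# analysis-population denominators, not-reported masking) are planted
# independently at configured per-study rates. Every planted perturbation
# is logged, so detection and classification can be scored against ground
# truth.

KIND_LABELS <- c(transposition = "error", percent_recalc = "error",
                 alt_arm = "selection", alt_timepoint = "selection",
                 denominator_policy = "selection", nr_mask = "not_reported")

#' Configuration for a synthetic extraction corpus
#'
#' Defaults mirror the packaged hip-arthroplasty corpus: six trials with
#' arm sizes between 20 and 100, comparator event risks between 5% and
#' 25%, a true relative risk of 1, three reviews, and per-study
#' perturbation rates of 5% per type.
#'
#' @param n_studies number of simulated trials.
#' @param arm_size_range integer interval for per-arm sample sizes.
#' @param baseline_risk_range event-probability interval for the
#'   comparator arm.
#' @param true_rr true relative risk (arm A risk = `true_rr` x arm B risk,
#'   capped at 1).
#' @param rate_transposition,rate_percent_recalc per-study probabilities of
#'   the two error-type perturbations.
#' @param rate_alt_arm,rate_alt_timepoint,rate_denominator_policy per-study
#'   probabilities of the three selection-type perturbations.
#' @param rate_nr per-study probability of masking a study as not
#'   reported.
#' @param alt_timepoint_risk_scale multiplier applied to both arms' risks
#'   when a review extracts data from a shorter follow-up horizon.
#' @param n_reviews total reviews including the reference.
#' @param seed integer seed; one pseudo-random stream per corpus, drawn in
#'   a fixed order (trials first, then reviews in index order).
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_studies = 6,
                              arm_size_range = c(20L, 100L),
                              baseline_risk_range = c(0.05, 0.25),
                              true_rr = 1,
                              rate_transposition = 0.05,
                              rate_percent_recalc = 0.05,
                              rate_alt_arm = 0.05,
                              rate_alt_timepoint = 0.05,
                              rate_denominator_policy = 0.05,
                              rate_nr = 0.05,
                              alt_timepoint_risk_scale = 0.5,
                              n_reviews = 3,
                              seed = 1L) {
  cfg <- list(n_studies = as.integer(n_studies),
              arm_size_range = as.integer(arm_size_range),
              baseline_risk_range = as.numeric(baseline_risk_range),
              true_rr = true_rr,
              rate_transposition = rate_transposition,
              rate_percent_recalc = rate_percent_recalc,
              rate_alt_arm = rate_alt_arm,
              rate_alt_timepoint = rate_alt_timepoint,
              rate_denominator_policy = rate_denominator_policy,
              rate_nr = rate_nr,
              alt_timepoint_risk_scale = alt_timepoint_risk_scale,
              n_reviews = as.integer(n_reviews),
              seed = as.integer(seed))
  rates <- unlist(cfg[grep("^rate_", names(cfg))])
  if (cfg$n_studies < 1) stop("n_studies must be >= 1", call. = FALSE)
  if (length(cfg$arm_size_range) != 2L ||
      cfg$arm_size_range[1] > cfg$arm_size_range[2] ||
      cfg$arm_size_range[1] < 2L)
    stop("arm_size_range must be an increasing interval with minimum >= 2",
         call. = FALSE)
  if (length(cfg$baseline_risk_range) != 2L ||
      cfg$baseline_risk_range[1] > cfg$baseline_risk_range[2] ||
      cfg$baseline_risk_range[1] < 0 || cfg$baseline_risk_range[2] > 1)
    stop("baseline_risk_range must be a probability interval", call. = FALSE)
  if (any(rates < 0 | rates > 1))
    stop("perturbation rates must lie in [0, 1]", call. = FALSE)
  if (cfg$true_rr <= 0) stop("true_rr must be positive", call. = FALSE)
  if (cfg$n_reviews < 1) stop("n_reviews must be >= 1", call. = FALSE)
  class(cfg) <- "simulation_config"
  cfg
}

sim_unit_ids <- function(n) sprintf("study_%03d", seq_len(n))
sim_review_ids <- function(n) c("reference", sprintf("review_%d", seq_len(n - 1)))

# Truth generation without touching the seed (corpus-level stream).
generate_truth_impl <- function(config) {
  n <- config$n_studies
  n1 <- sample(config$arm_size_range[1]:config$arm_size_range[2], n,
               replace = TRUE)
  n2 <- sample(config$arm_size_range[1]:config$arm_size_range[2], n,
               replace = TRUE)
  p_b <- stats::runif(n, config$baseline_risk_range[1],
                      config$baseline_risk_range[2])
  p_a <- pmin(1, config$true_rr * p_b)
  a <- stats::rbinom(n, n1, p_a)
  c <- stats::rbinom(n, n2, p_b)
  ext <- data.frame(review_id = sim_review_ids(2)[1],
                    study_unit_id = sim_unit_ids(n),
                    outcome_id = "dislocation",
                    timepoint = "unspecified",
                    arm_a_events = a, arm_a_total = n1,
                    arm_b_events = c, arm_b_total = n2,
                    status = "reported",
                    stringsAsFactors = FALSE)
  attr(ext, "latent") <- data.frame(study_unit_id = ext$study_unit_id,
                                    p_a = p_a, p_b = p_b,
                                    stringsAsFactors = FALSE)
  ext
}

#' Simulate the reference review's (correct) trial extractions
#'
#' @param config a [simulation_config()].
#' @return Extraction data.frame for the reference review, one row per
#'   simulated trial, with the latent per-arm risks attached as attribute
#'   `latent`. Deterministic given `config$seed`.
#' @export
generate_truth_trials <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  generate_truth_impl(config)
}

apply_kind <- function(row, kind, config, latent) {
  p_a <- latent$p_a[latent$study_unit_id == row$study_unit_id]
  p_b <- latent$p_b[latent$study_unit_id == row$study_unit_id]
  switch(kind,
    transposition = {
      tmp <- row$arm_a_total
      row$arm_a_total <- row$arm_b_total
      row$arm_b_total <- tmp
      row
    },
    percent_recalc = {
      # the review re-derives counts from rounded percentages applied to
      # denominators that are off by one
      for (arm in c("a", "b")) {
        ev <- row[[paste0("arm_", arm, "_events")]]
        tot <- row[[paste0("arm_", arm, "_total")]]
        pct <- round(100 * ev / tot)
        shifted <- tot + 1L
        row[[paste0("arm_", arm, "_events")]] <-
          min(as.integer(round(shifted * pct / 100)), shifted)
        row[[paste0("arm_", arm, "_total")]] <- shifted
      }
      row
    },
    alt_arm = {
      n2 <- sample(config$arm_size_range[1]:config$arm_size_range[2], 1L)
      row$arm_b_total <- n2
      row$arm_b_events <- stats::rbinom(1L, n2, p_b)
      row
    },
    alt_timepoint = {
      s <- config$alt_timepoint_risk_scale
      row$arm_a_events <- stats::rbinom(1L, row$arm_a_total, min(1, p_a * s))
      row$arm_b_events <- stats::rbinom(1L, row$arm_b_total, min(1, p_b * s))
      row
    },
    denominator_policy = {
      d_a <- sample(1:5, 1L)
      d_b <- sample(1:5, 1L)
      row$arm_a_total <- max(row$arm_a_events, row$arm_a_total - d_a)
      row$arm_b_total <- max(row$arm_b_events, row$arm_b_total - d_b)
      row
    },
    nr_mask = {
      row$status <- "not_reported"
      row[COUNT_COLS] <- NA_integer_
      row
    })
}

kind_variables <- function(kind) {
  switch(kind,
    transposition = c("arm_a_total", "arm_b_total"),
    percent_recalc = VARIABLES,
    alt_arm = c("arm_b_events", "arm_b_total"),
    alt_timepoint = c("arm_a_events", "arm_b_events"),
    denominator_policy = c("arm_a_total", "arm_b_total"),
    nr_mask = VARIABLES)
}

perturb_impl <- function(truth, config, review_id) {
  latent <- attr(truth, "latent")
  if (is.null(latent))
    stop("truth extractions must carry the 'latent' attribute from generate_truth_trials()",
         call. = FALSE)
  rates <- c(transposition = config$rate_transposition,
             percent_recalc = config$rate_percent_recalc,
             alt_arm = config$rate_alt_arm,
             alt_timepoint = config$rate_alt_timepoint,
             denominator_policy = config$rate_denominator_policy,
             nr_mask = config$rate_nr)
  ext <- truth
  ext$review_id <- review_id
  records <- list()
  for (i in seq_len(nrow(ext))) {
    apply_flags <- stats::runif(length(rates)) < rates
    names(apply_flags) <- names(rates)
    row <- ext[i, , drop = FALSE]
    for (kind in names(rates)) {
      if (!apply_flags[[kind]]) next
      if (row$status == "not_reported" && kind != "nr_mask") next
      before <- row
      row <- apply_kind(row, kind, config, latent)
      vars <- kind_variables(kind)
      changed <- if (kind == "nr_mask") TRUE else
        any(unlist(row[vars]) != unlist(before[vars]))
      records[[length(records) + 1L]] <- data.frame(
        review_id = review_id,
        study_unit_id = row$study_unit_id,
        outcome_id = row$outcome_id,
        variables = paste(vars, collapse = ";"),
        kind = kind,
        true_label = KIND_LABELS[[kind]],
        effective = changed,
        stringsAsFactors = FALSE)
    }
    ext[i, ] <- row
  }
  records <- if (length(records)) do.call(rbind, records) else
    data.frame(review_id = character(), study_unit_id = character(),
               outcome_id = character(), variables = character(),
               kind = character(), true_label = character(),
               effective = logical(), stringsAsFactors = FALSE)
  rownames(records) <- NULL
  list(extractions = ext, records = records)
}

#' Perturb the reference extractions into one synthetic review
#'
#' Each perturbation type is applied to each study independently with its
#' configured rate, in the fixed order transposition, percent_recalc,
#' alt_arm, alt_timepoint, denominator_policy, nr_mask. A perturbation
#' that happens to reproduce the original values (e.g. a transposition
#' with equal arm sizes) is logged with `effective = FALSE`.
#'
#' @param truth output of [generate_truth_trials()].
#' @param config the [simulation_config()].
#' @param review_index positive integer; review `r` draws from the stream
#'   seeded with `seed + r`, so a review is reproducible standalone or as
#'   part of [generate_corpus()].
#' @return list with `extractions` (the perturbed copy) and `records`
#'   (one logged row per applied perturbation: study, perturbation kind,
#'   affected variables, the implied taxonomy label, and whether it
#'   changed any stored value).
#' @export
perturb_review <- function(truth, config, review_index) {
  stopifnot(inherits(config, "simulation_config"), review_index >= 1)
  if (nrow(truth) == 0L) stop("truth extractions are empty", call. = FALSE)
  set.seed(config$seed + as.integer(review_index))
  perturb_impl(truth, config,
               sim_review_ids(review_index + 1L)[review_index + 1L])
}

#' Generate a full synthetic audit corpus with ground truth
#'
#' Review 0 is the unperturbed reference; reviews 1 to `n_reviews - 1` are
#' perturbed independently. Annotations are auto-derived from the
#' perturbation log: every variable whose stored value ends up different
#' from the truth is labelled with the taxonomy label of the last
#' perturbation that touched it, so [check_annotation_consistency()] is
#' empty by construction.
#'
#' @param config a [simulation_config()] with `n_reviews >= 2`.
#' @return list with `corpus` (an [audit_corpus()]) and `records` (all
#'   reviews' perturbation logs).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_reviews < 2)
    stop("n_reviews must be >= 2 to form a corpus", call. = FALSE)
  truth <- generate_truth_trials(config)
  extractions <- truth
  all_records <- list()
  annotations <- list()
  for (r in seq_len(config$n_reviews - 1L)) {
    pr <- perturb_review(truth, config, r)
    extractions <- rbind(extractions, pr$extractions)
    all_records[[r]] <- pr$records
    annotations[[r]] <- derive_annotations(truth, pr$extractions, pr$records)
  }
  records <- do.call(rbind, all_records)
  ann <- do.call(rbind, annotations)
  units <- data.frame(unit_id = truth$study_unit_id,
                      member_publications = "", notes = "synthetic",
                      stringsAsFactors = FALSE)
  corpus <- audit_corpus(extractions, sim_review_ids(2)[1],
                         annotations = ann, study_units = units)
  list(corpus = corpus, records = records)
}

# Annotate every variable whose perturbed value differs from the truth,
# using the label of the last perturbation whose affected set contains it.
derive_annotations <- function(truth, perturbed, records) {
  out <- list()
  for (i in seq_len(nrow(perturbed))) {
    prow <- perturbed[i, ]
    if (prow$status == "not_reported") next
    trow <- truth[truth$study_unit_id == prow$study_unit_id, ]
    rec <- records[records$study_unit_id == prow$study_unit_id, , drop = FALSE]
    for (v in VARIABLES) {
      if (prow[[v]] == trow[[v]]) next
      hits <- rec[vapply(strsplit(rec$variables, ";"),
                         function(vs) v %in% vs, logical(1)), , drop = FALSE]
      if (nrow(hits) == 0L) next  # should not happen: unexplained diff
      out[[length(out) + 1L]] <- data.frame(
        review_id = prow$review_id, study_unit_id = prow$study_unit_id,
        outcome_id = prow$outcome_id, variable = v,
        label = hits$true_label[nrow(hits)],
        adjudicated = FALSE,
        rationale = paste0("synthetic: ", hits$kind[nrow(hits)]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else empty_annotations()
}
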