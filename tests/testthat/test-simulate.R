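test_that("generation is deterministic under a fixed seed", {
  cfg <- simulation_config(n_studies = 10, seed = 42)
  s1 <- generate_corpus(cfg)
  s2 <- generate_corpus(cfg)
  expect_equal(s1$corpus$extractions, s2$corpus$extractions)
  expect_equal(s1$records, s2$records)
  # truth generated standalone matches the corpus reference rows
  truth <- generate_truth_trials(cfg)
  ref_rows <- s1$corpus$extractions[
    s1$corpus$extractions$review_id == "reference", ]
  expect_equal(ref_rows$arm_a_events, truth$arm_a_events)

  # a perturbed review regenerated standalone matches the corpus
  pr <- perturb_review(truth, cfg, 1)
  rev_rows <- s1$corpus$extractions[
    s1$corpus$extractions$review_id == "review_1", ]
  rownames(rev_rows) <- NULL
  rownames(pr$extractions) <- NULL
  expect_equal(rev_rows, pr$extractions, ignore_attr = TRUE)
})

test_that("degenerate configurations behave as specified", {
  expect_error(simulation_config(n_studies = 0), "n_studies")
  expect_error(simulation_config(arm_size_range = c(10, 5)), "arm_size_range")
  expect_error(simulation_config(rate_nr = 1.5), "rates")

  # zero baseline risk: no events anywhere
  cfg0 <- simulation_config(baseline_risk_range = c(0, 0), seed = 5)
  truth <- generate_truth_trials(cfg0)
  expect_true(all(truth$arm_a_events == 0))
  expect_true(all(truth$arm_b_events == 0))
})

test_that("null perturbation rates reproduce the truth exactly", {
  cfg <- simulation_config(n_studies = 8,
                           rate_transposition = 0, rate_percent_recalc = 0,
                           rate_alt_arm = 0, rate_alt_timepoint = 0,
                           rate_denominator_policy = 0, rate_nr = 0,
                           seed = 9)
  sim <- generate_corpus(cfg)
  expect_equal(nrow(sim$records), 0)
  expect_equal(nrow(sim$corpus$annotations), 0)
  for (r in c("review_1", "review_2")) {
    s <- audit_outcome(sim$corpus, r, "dislocation")
    expect_equal(s$n_error + s$n_selection, 0)
    expect_equal(c(s$pct_error, s$pct_selection), c(0, 0))
  }
  rep <- impact_report(sim$corpus)
  expect_true(all(rep$log_rr_difference == 0))
  expect_true(all(!rep$flip))
})

test_that("forced transposition swaps every unequal pair of totals", {
  cfg <- simulation_config(n_studies = 12, rate_transposition = 1,
                           rate_percent_recalc = 0, rate_alt_arm = 0,
                           rate_alt_timepoint = 0,
                           rate_denominator_policy = 0, rate_nr = 0,
                           seed = 13)
  truth <- generate_truth_trials(cfg)
  pr <- perturb_review(truth, cfg, 1)
  expect_true(all(pr$records$kind == "transposition"))
  expect_equal(nrow(pr$records), 12)
  expect_equal(pr$extractions$arm_a_total, truth$arm_b_total)
  expect_equal(pr$extractions$arm_b_total, truth$arm_a_total)
  # ineffective when arm sizes happen to be equal
  expect_equal(pr$records$effective,
               truth$arm_a_total != truth$arm_b_total)
})

test_that("per-kind perturbation frequencies match their configured rates", {
  cfg <- simulation_config(n_studies = 200, arm_size_range = c(30, 80),
                           rate_transposition = 0.2, rate_percent_recalc = 0.2,
                           rate_alt_arm = 0.2, rate_alt_timepoint = 0.2,
                           rate_denominator_policy = 0.2, rate_nr = 0.2,
                           n_reviews = 2, seed = 17)
  sim <- generate_corpus(cfg)
  rec <- sim$records
  # nr_mask suppresses later kinds only (it is applied last), so every
  # kind is sampled on all 200 studies
  freq <- table(factor(rec$kind, levels = names(extractaudit:::KIND_LABELS))) / 200
  expect_true(all(abs(freq - 0.2) <= 0.05))
})

test_that("every effective perturbation is detected and nothing else", {
  # recall 1.0 on value-changing perturbations, no false positives
  for (seed in c(1, 2, 3)) {
    cfg <- simulation_config(n_studies = 40, rate_transposition = 0.15,
                             rate_percent_recalc = 0.15, rate_alt_arm = 0.15,
                             rate_alt_timepoint = 0.15,
                             rate_denominator_policy = 0.15, rate_nr = 0.1,
                             n_reviews = 3, seed = seed)
    sim <- generate_corpus(cfg)
    truth <- sim$corpus$extractions[
      sim$corpus$extractions$review_id == "reference", ]
    expect_equal(nrow(check_annotation_consistency(sim$corpus)), 0)
    for (rev in setdiff(sim$corpus$reviews, "reference")) {
      rows <- sim$corpus$extractions[sim$corpus$extractions$review_id == rev, ]
      for (i in seq_len(nrow(rows))) {
        if (rows$status[i] == "not_reported") next
        trow <- truth[truth$study_unit_id == rows$study_unit_id[i], ]
        cmp <- compare_study(rows[i, ], trow, sim$corpus$annotations)
        truly_changed <- vapply(VARIABLES, function(v)
          rows[i, v] != trow[[v]], logical(1))
        expect_equal(cmp$differs, unname(truly_changed))
        # detected differences carry their planted taxonomy label
        expect_true(all(cmp$label[cmp$differs] %in% c("error", "selection")))
        expect_true(all(cmp$label[!cmp$differs] == "identical"))
      }
    }
  }
})

test_that("selection-only perturbations produce zero error rates", {
  cfg <- simulation_config(n_studies = 30, rate_transposition = 0,
                           rate_percent_recalc = 0, rate_alt_arm = 0.4,
                           rate_alt_timepoint = 0.4,
                           rate_denominator_policy = 0.4, rate_nr = 0,
                           n_reviews = 2, seed = 23)
  sim <- generate_corpus(cfg)
  s <- audit_outcome(sim$corpus, "review_1", "dislocation")
  expect_equal(s$n_error, 0)
  expect_equal(s$pct_error, 0)
  expect_gt(s$n_selection, 0)
})

test_that("the unperturbed pooled estimate recovers the true relative risk", {
  # Monte Carlo: mean pooled log RR near log(true_rr)
  cfg <- simulation_config(n_studies = 6, true_rr = 1, seed = 31)
  mus <- vapply(cfg$seed + seq_len(300), function(s) {
    cfg$seed <- s
    truth <- generate_truth_trials(cfg)
    ests <- lapply(seq_len(nrow(truth)), function(i)
      effect_from_table(truth$arm_a_events[i], truth$arm_a_total[i],
                        truth$arm_b_events[i], truth$arm_b_total[i]))
    if (all(vapply(ests, `[[`, logical(1), "excluded"))) return(NA_real_)
    pool_random_effects(ests)$log_rr
  }, numeric(1))
  expect_lt(abs(mean(mus, na.rm = TRUE)), 0.05)
})
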