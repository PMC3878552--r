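test_that("compare_study flags exactly the discrepant variables", {
  corpus <- load_fixture_corpus()
  # Keating dislocation: review 3/69 vs 3/111 against reference 3/69 vs 2/69
  rev <- find_extraction(corpus, "BMJ", "keating_2006", "dislocation")
  ref <- find_extraction(corpus, "HTA", "keating_2006", "dislocation")
  cmp <- compare_study(rev, ref, corpus$annotations)
  expect_equal(cmp$variable[cmp$differs],
               c("arm_b_events", "arm_b_total"))
  expect_equal(cmp$label[cmp$differs], c("selection", "selection"))
  expect_equal(cmp$label[!cmp$differs], c("identical", "identical"))

  # identical records: nothing differs
  cmp_id <- compare_study(ref, ref)
  expect_false(any(cmp_id$differs))
  expect_true(all(cmp_id$label == "identical"))

  # review NR: all four labelled not_reported
  nr <- find_extraction(corpus, "BMJ", "mouzopoulos_2008", "dislocation")
  cmp_nr <- compare_study(nr, ref_nr <- find_extraction(
    corpus, "HTA", "mouzopoulos_2008", "dislocation"))
  expect_true(all(cmp_nr$label == "not_reported"))
  expect_false(any(cmp_nr$differs))

  # mismatched units refuse to compare
  expect_error(compare_study(rev, find_extraction(corpus, "HTA", "dorr_1986",
                                                  "dislocation")),
               "different study units")
})

test_that("unannotated cells default to identical/error, with a warning when the reference is NR", {
  ext <- rbind(ext_row("ref", "u1", a = 5, n1 = 50, b = 4, n2 = 40),
               ext_row("rev", "u1", a = 6, n1 = 50, b = 4, n2 = 40))
  corpus <- audit_corpus(ext, "ref")
  cmp <- compare_study(corpus$extractions[2, ], corpus$extractions[1, ])
  expect_equal(cmp$label, c("error", "identical", "identical", "identical"))

  ext2 <- rbind(ext_row("ref", "u1"),
                ext_row("rev", "u1", a = 6, n1 = 50, b = 4, n2 = 40))
  corpus2 <- audit_corpus(ext2, "ref")
  ws <- capture_warnings(
    cmp2 <- compare_study(corpus2$extractions[2, ], corpus2$extractions[1, ]))
  expect_length(ws, 4)  # one per unannotated variable
  expect_match(ws, "defaulting to 'error'", all = TRUE)
  expect_true(all(cmp2$label == "error"))
  expect_true(all(cmp2$differs))
})

test_that("audit_outcome reproduces the published footer difference rates", {
  corpus <- load_fixture_corpus()
  check <- function(review, outcome, err, sel, pct_err, pct_sel, n_vars) {
    s <- audit_outcome(corpus, review, outcome)
    expect_equal(s$n_variables, n_vars)
    expect_equal(s$n_error, err)
    expect_equal(s$n_selection, sel)
    expect_equal(s$pct_error, pct_err)
    expect_equal(s$pct_selection, pct_sel)
  }
  check("BMJ", "dislocation", 2, 4, 8, 17, 24)
  check("Cochrane", "dislocation", 2, 2, 8, 8, 24)
  check("BMJ", "mortality_1y", 4, 10, 17, 42, 24)
  check("Cochrane", "mortality_1y", 2, 4, 13, 25, 16)
  check("BMJ", "revision", 3, 5, 13, 21, 24)
  check("Cochrane", "revision", 2, 6, 8, 25, 24)
})

test_that("audit refuses the reference review and degrades sanely", {
  corpus <- load_fixture_corpus()
  expect_error(audit_outcome(corpus, "HTA", "dislocation"),
               "must differ from the reference")
  expect_error(audit_outcome(corpus, "nope", "dislocation"), "unknown review")

  # review identical to reference everywhere: zero counts
  ext <- rbind(ext_row("ref", "u1", a = 5, n1 = 50, b = 4, n2 = 40),
               ext_row("rev", "u1", a = 5, n1 = 50, b = 4, n2 = 40))
  s <- audit_outcome(audit_corpus(ext, "ref"), "rev", "dislocation")
  expect_equal(s$n_error + s$n_selection, 0)
  expect_equal(c(s$pct_error, s$pct_selection), c(0, 0))

  # review never reports the outcome: empty summary
  s2 <- audit_outcome(audit_corpus(ext, "ref"), "rev", "revision")
  expect_equal(s2$n_variables, 0)
  expect_equal(s2$pct_error, 0)
})

test_that("label counts partition the compared variables and are order-invariant", {
  corpus <- load_fixture_corpus()
  for (review in c("BMJ", "Cochrane")) for (outcome in OUTCOMES) {
    s <- audit_outcome(corpus, review, outcome)
    expect_equal(s$n_identical + s$n_error + s$n_selection + s$n_not_reported,
                 4 * s$n_units_analysed)
  }
  shuffled <- corpus
  set.seed(7)
  shuffled$extractions <- shuffled$extractions[sample(nrow(shuffled$extractions)), ]
  expect_equal(difference_rate_table(shuffled),
               difference_rate_table(corpus))
})

test_that("difference counts agree with exhaustive enumeration on small corpora", {
  # independent oracle: count unequal variable pairs by brute force
  set.seed(11)
  for (rep in 1:20) {
    n_units <- sample(1:3, 1)
    units <- paste0("u", seq_len(n_units))
    mk <- function(review) do.call(rbind, lapply(units, function(u)
      ext_row(review, u, a = sample(0:5, 1), n1 = 10,
              b = sample(0:5, 1), n2 = 12)))
    ref <- mk("ref"); rev <- mk("rev")
    corpus <- audit_corpus(rbind(ref, rev), "ref")
    s <- suppressWarnings(audit_outcome(corpus, "rev", "dislocation"))
    oracle <- 0L
    for (u in units) for (v in VARIABLES)
      oracle <- oracle + (rev[rev$study_unit_id == u, v] !=
                            ref[ref$study_unit_id == u, v])
    # unannotated differences default to label "error"
    expect_equal(s$n_error, oracle)
    expect_equal(s$n_identical, 4L * n_units - oracle)
  }
})

test_that("round-half-up matches the published percentage arithmetic", {
  expect_equal(round_half_up(100 * 4 / 24), 17)
  expect_equal(round_half_up(100 * 10 / 24), 42)
  expect_equal(round_half_up(100 * 2 / 16), 13)
  expect_equal(round_half_up(100 * 3 / 24), 13)
  expect_equal(round_half_up(12.5), 13)  # base round() would give 12
})

test_that("annotation-consistency checker is empty on the fixture and catches planted faults", {
  corpus <- load_fixture_corpus()
  expect_equal(nrow(check_annotation_consistency(corpus)), 0)

  # identical label on differing values
  bad1 <- corpus
  i <- which(bad1$annotations$review_id == "BMJ" &
               bad1$annotations$study_unit_id == "keating_2006" &
               bad1$annotations$outcome_id == "dislocation" &
               bad1$annotations$variable == "arm_b_total")
  bad1$annotations$label[i] <- "identical"
  r1 <- check_annotation_consistency(bad1)
  expect_equal(nrow(r1), 1)
  expect_match(r1$problem, "values that differ")

  # selection label on an NR review cell
  bad2 <- corpus
  bad2$annotations <- rbind(bad2$annotations,
                            ann_row("BMJ", "mouzopoulos_2008", "arm_a_events",
                                    "selection"))
  r2 <- check_annotation_consistency(bad2)
  expect_equal(nrow(r2), 1)
  expect_match(r2$problem, "not reported")

  # selection label on equal, unadjudicated values
  bad3 <- corpus
  bad3$annotations <- rbind(bad3$annotations,
                            ann_row("BMJ", "dorr_1986", "arm_a_events",
                                    "selection"))
  expect_equal(nrow(check_annotation_consistency(bad3)), 1)
})
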