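# In-code builders for small corpora used across tests.

ext_row <- function(review, unit, outcome = "dislocation",
                    timepoint = "unspecified",
                    a = NA, n1 = NA, b = NA, n2 = NA,
                    status = if (is.na(a)) "not_reported" else "reported") {
  data.frame(review_id = review, study_unit_id = unit, outcome_id = outcome,
             timepoint = timepoint,
             arm_a_events = as.integer(a), arm_a_total = as.integer(n1),
             arm_b_events = as.integer(b), arm_b_total = as.integer(n2),
             status = status, stringsAsFactors = FALSE)
}

ann_row <- function(review, unit, variable, label, outcome = "dislocation",
                    adjudicated = FALSE, rationale = "") {
  data.frame(review_id = review, study_unit_id = unit, outcome_id = outcome,
             variable = variable, label = label, adjudicated = adjudicated,
             rationale = rationale, stringsAsFactors = FALSE)
}

# Two reviews, three units: u1 identical, u2 differs in both arm-B
# variables (annotated selection), u3 not reported by the review.
make_mini_corpus <- function() {
  ext <- rbind(
    ext_row("ref", "u1", a = 5, n1 = 50, b = 4, n2 = 40),
    ext_row("ref", "u2", a = 3, n1 = 69, b = 2, n2 = 69),
    ext_row("ref", "u3", a = 1, n1 = 20, b = 2, n2 = 20),
    ext_row("rev", "u1", a = 5, n1 = 50, b = 4, n2 = 40),
    ext_row("rev", "u2", a = 3, n1 = 69, b = 3, n2 = 111),
    ext_row("rev", "u3"))
  ann <- rbind(
    ann_row("rev", "u2", "arm_b_events", "selection"),
    ann_row("rev", "u2", "arm_b_total", "selection"))
  audit_corpus(ext, "ref", annotations = ann)
}

expect_pooled_close <- function(res, rr, lo, hi, p, tol_rr = 0.005,
                                tol_p = 0.01) {
  expect_equal(res$rr, rr, tolerance = tol_rr / rr)
  expect_equal(res$ci_low, lo, tolerance = tol_rr / lo)
  expect_equal(res$ci_high, hi, tolerance = tol_rr / hi)
  expect_lt(abs(res$p - p), tol_p)
}
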