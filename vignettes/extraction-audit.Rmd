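---
title: "Auditing binary outcome data extraction across systematic reviews"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing binary outcome data extraction across systematic reviews}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(extractaudit)
```

## The problem

Data extraction is the stage of a systematic review that produces the
numbers everything downstream depends on, yet it is rarely audited.
For simple binary outcome data the unit of comparison is crisp: per
trial, per outcome, a review extracts four variables — events and total
in the index arm and in the comparator arm. Two reviews of the same
trial either extracted the same four numbers or they did not. When they
did not, there are exactly two explanations:

* an **error**: the value matches nothing the primary publication
  reports — a denominator transposed between arms, or a numerator
  recalculated from a rounded percentage; or
* a **selection difference**: the value is a genuine alternative datum —
  a different trial arm, a different follow-up timepoint, a different
  analysis population (e.g. intention-to-treat versus per-protocol
  denominators) — chosen, usually, without stated rationale.

`extractaudit` operationalises this audit: it stores the extractions of
several reviews over shared study units, compares each review against a
designated reference standard variable by variable, aggregates the
classified discrepancies into per-outcome percentage rates, and then
asks the question that matters — do the discrepancies move the pooled
treatment-effect estimates, and do they change any qualitative
conclusion?

## The corpus model

An `audit_corpus` holds four tables: extraction rows (one per review ×
study unit × outcome × timepoint), the study-unit register, the
annotation table, and the reference review's identity.

Two modelling choices deserve explanation.

**Not-reported cells are explicit.** A review that omitted a study is
stored as a row with `status = "not_reported"`, never as a missing row.
The audit needs to distinguish "the review chose not to analyse this
trial" (which removes the unit from that review's denominator) from "the
file is incomplete" (which is an error in corpus preparation and is
caught by validation).

**Multi-publication cohorts are one unit.** In the packaged corpus the
Skinner 1989 and Ravikumar 2000 publications report the same randomised
cohort at one and thirteen years; they are a single study unit with two
timepoints. Reviews are compared like with like: a review that analysed
the thirteen-year data is compared against the reference's thirteen-year
extraction. Pooled analyses at "one year" use the one-year dataset for
this unit and pooled analyses at "thirteen years" substitute the
thirteen-year dataset; trials reported at a single unspecified timepoint
contribute their one dataset to both.

## The annotation layer and adjudication

The package deliberately does not decide whether a discrepant value is
an error or a selection: that judgement requires reading the primary
trial publications and is supplied as an annotation per variable. The
comparison engine computes only the `differs` flag; labels default to
`identical`/`error` when no annotation exists, and the
`check_annotation_consistency()` checker verifies that every supplied
label is compatible with the stored values.

One extension to the obvious scheme proved necessary: the `adjudicated`
flag. Two situations arise in real audits that a pure value-comparison
cannot express:

1. *The reference itself is silent.* For one-year mortality in the
   packaged corpus, two trials are not reported by the reference review
   but are analysed by another review. Whether that review's values are
   right or wrong can only be decided against the primary publications.
   Annotations on such variables must be adjudicated, and may even be
   `identical` (the value matches the primary report) without any
   in-corpus reference to compare against.
2. *Both reviews are wrong in the same way.* A numerator recalculated
   from a rounded percentage can coincide numerically with the reference
   value while still not being a number the primary publication ever
   reported. An adjudicated `error` or `selection` label on value-equal
   cells records exactly this.

Unannotated variables whose reference cell is missing default to `error`
with a warning — silent optimism would understate the problem being
audited.

## Difference rates

`audit_outcome()` counts labels over the units the review analysed: the
denominator is 4 × (analysed units), so a review that reports only four
of six trials for an outcome is scored out of 16, not 24. Percentages
are rounded half-up to integers (12.5% reports as 13%), matching how
such rates are conventionally printed. On the packaged corpus:

```{r}
corpus <- load_fixture_corpus()
difference_rate_table(corpus)
```

Selection differences outnumber errors for every review and outcome —
the central empirical observation this audit design is built to surface.
For the revision outcome the per-cell data yield 5 selection differences
for the BMJ review (21%) and 6 for the Cochrane review (25%); the
printed source these data were transcribed from carries a footer that
transposes the two, and the corpus follows the cells.

## The meta-analysis engine

Pooling is relative-risk, random-effects, on the log scale:
`y = ln((a/n1)/(c/n2))` with variance `1/a − 1/n1 + 1/c − 1/n2`,
DerSimonian–Laird moment estimate of the between-study variance, weights
`1/(v + τ²)`, a fixed 1.96 normal CI multiplier and a two-sided normal
p-value. This engine is written in the package (and cross-checked
against `metafor` in the test suite) because the pooled numbers are the
package's measurement instrument: the audit's impact claims rest on
them, so their every numerical choice is pinned down here.

Numerical policies:

* **Double-zero trials** carry no information about a ratio of risks
  and are excluded (with the exclusion recorded on the result).
* **Single-zero trials** receive the standard continuity correction of
  0.5 per event cell — equivalently 0.5 added to all four cells of the
  2×2 table, so totals grow by 1. `correction = "none"` disables this,
  excluding such trials instead.
* **τ² truncation** at zero, per the moment estimator; with τ² = 0 the
  random-effects mean reduces exactly to the fixed-effect mean, a
  property the tests assert.
* The **CI multiplier is 1.96**, not a t or Knapp–Hartung quantile:
  with at most six small trials per pool, the normal interval is the
  convention the audited reviews themselves used, and significance
  judgements are made on the CI rather than on rounded p-values.
* A **Mantel–Haenszel fixed-effect** pool (Greenland–Robins variance)
  is provided as a cross-check mode, since small-trial inverse-variance
  weighting is the main methodological criticism such a grid invites.

```{r}
meta_table(corpus, exclusions = fixture_meta_exclusions())
```

### The one analysis-set exclusion

Every cell of the pooled grid follows mechanically from the corpus
except one. In the Cochrane revision pool the Blomfeldt trial enters as
1/60 vs 0/60 — but the single counted event was a wound revision, not a
revision of the implant, which is the outcome every other cell counts
(the corpus annotation records this). The published pooled analysis of
that column evidently dropped the trial: with it the pooled RR is 0.45
(0.21–0.98), without it 0.40 (0.18–0.89), the published value, which
this package reproduces to publication precision. The exclusion ships as
data — `fixture_meta_exclusions()` — and is passed explicitly wherever
the published grid is being reproduced, rather than being wired into the
engine; a sensitivity exclusion should be visible at every call site.

## Impact: does any conclusion flip?

`impact_report()` compares each non-reference review's pooled result
against the reference per outcome and timepoint. Besides the magnitude
of the shift (|difference in log RR|) it reports the *significance
flip*: whether exactly one of the two 95% CIs excludes 1. Significance
is judged on the interval, not the printed p-value, because intervals
are the finer-grained evidence once results are rounded. No formal test
of the difference between two pooled estimates is attempted — the two
pools share most of their data, and the audit's question is descriptive.

```{r}
rep <- impact_report(corpus, exclusions = fixture_meta_exclusions())
rep[, c("outcome_id", "timepoint", "review_b", "rr_a", "rr_b", "flip")]
```

One flip: thirteen-year revision, where the reference extraction gives a
clearly protective pooled RR and the BMJ extraction's interval just
crosses 1.

## The synthetic generator

Real audit corpora cannot validate detection machinery — their ground
truth is unknown. `generate_corpus()` therefore builds corpora with
known truth: a reference review extracts the correct counts of `n`
simulated two-arm trials, and each further review is a perturbed copy.
The six perturbation types mirror the discrepancy mechanisms observed in
real extractions, with a fixed type→taxonomy mapping:

| kind | what it does | label |
|---|---|---|
| `transposition` | swaps the two arm totals | error |
| `percent_recalc` | recomputes events from rounded percentages on off-by-one denominators | error |
| `alt_arm` | substitutes a freshly simulated comparator arm | selection |
| `alt_timepoint` | re-simulates events at a shorter horizon (risks × 0.5) | selection |
| `denominator_policy` | removes 1–5 participants per arm total | selection |
| `nr_mask` | masks the study as not reported | not_reported |

Defaults mirror the packaged corpus: 6 trials, arm sizes 20–100,
comparator risks 5–25%, true RR 1, three reviews, 5% per-type rates —
the scale of corpus a hand-built audit of overlapping reviews actually
has. The 0.5 risk scaling for `alt_timepoint` is arbitrary but fixed and
configurable; only the perturbation *type* is empirically motivated.
Randomness is one stream per corpus with a documented draw order (trials
first, then reviews in index order; review *r* draws from `seed + r`),
so a review regenerated standalone matches the corpus build exactly.

What the generator does *not* emulate: correlated perturbations (real
reviews err systematically, e.g. the same transposition across all three
outcomes of one trial), disagreement between human annotators, and
outcome-definition ambiguity. Passing the synthetic suites therefore
shows the machinery is correct — detection recall 1.0 on
value-changing perturbations, no false positives, exact label recovery,
0% rates and zero impact under null perturbation, and ~95% CI coverage
at true RR 1 — not that any particular real corpus is error-free.

## Problem sizes and test design

The test suite enumerates small corpora exhaustively (≤3 units) as an
independent oracle for the difference counts, cross-checks the DL and
MH engines against `metafor` on random zero-free tables, and sizes the
Monte-Carlo checks at 300 replicates for mean-log-RR recovery and 500
simulated meta-analyses (6 trials each) for CI coverage, with a ±3
percentage-point band around the nominal 95% — wide enough for binomial
noise at 500 replicates, tight enough to catch a mis-specified variance
formula.

## Limitations

* The taxonomy is binary by design; values that are simultaneously
  mis-selected and mis-transcribed are counted once, under their
  annotated label.
* Difference rates treat variables as exchangeable: a transposed
  denominator of 91 counts the same as a numerator that changes the
  event count by a factor of two. The impact layer, not the rate, is
  where magnitude lives.
* With at most six trials per pool, τ² is weakly identified and often
  truncates to zero; the pooled intervals are accordingly approximate,
  which is one more reason significance flips near the boundary should
  be read as fragility, not as contradiction.
* The reference standard is a convention, not a verdict: the package
  measures inconsistency between extractions, and only the adjudicated
  annotations say anything about which side is right.
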