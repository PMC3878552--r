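# Random-effects relative-risk meta-analysis (DerSimonian-Laird) with a
# Mantel-Haenszel fixed-effect cross-check.
#
# The impact of extraction discrepancies is measured by re-pooling each
# review's extracted 2x2 tables. Everything is computed on the log
# relative-risk scale: y = ln((a/n1)/(c/n2)), v = 1/a - 1/n1 + 1/c - 1/n2.
# A trial with zero events in both arms carries no information about the
# relative risk and is excluded; a trial with a zero in exactly one arm
# receives the standard continuity correction of 0.5 added to both event
# cells and 1 to both totals (i.e. 0.5 to every cell of the 2x2 table).

#' Log relative risk and its variance from one 2x2 table
#'
#' @param events_a,total_a events and total in arm A (index treatment).
#' @param events_b,total_b events and total in arm B (comparator).
#' @param correction `"half"` (default) applies the 0.5/1 continuity
#'   correction to single-zero tables; `"none"` leaves zeros in place
#'   (such tables are then excluded as incalculable).
#' @return A list of class `effect_estimate`: `log_rr`, `var_log_rr`,
#'   `rr`, `corrected`, `excluded`, `reason`.
#' @export
effect_from_table <- function(events_a, total_a, events_b, total_b,
                              correction = c("half", "none")) {
  correction <- match.arg(correction)
  stopifnot(total_a > 0, total_b > 0,
            events_a >= 0, events_a <= total_a,
            events_b >= 0, events_b <= total_b)
  a <- events_a; n1 <- total_a; c <- events_b; n2 <- total_b
  corrected <- FALSE
  excluded <- FALSE
  reason <- NA_character_
  if (a == 0 && c == 0) {
    excluded <- TRUE
    reason <- "double_zero"
  } else if (a == 0 || c == 0) {
    if (correction == "half") {
      a <- a + 0.5; c <- c + 0.5; n1 <- n1 + 1; n2 <- n2 + 1
      corrected <- TRUE
    } else {
      excluded <- TRUE
      reason <- "single_zero_uncorrected"
    }
  }
  if (excluded) {
    est <- list(log_rr = NA_real_, var_log_rr = NA_real_, rr = NA_real_,
                corrected = FALSE, excluded = TRUE, reason = reason)
  } else {
    log_rr <- log((a / n1) / (c / n2))
    var_log_rr <- 1 / a - 1 / n1 + 1 / c - 1 / n2
    est <- list(log_rr = log_rr, var_log_rr = var_log_rr,
                rr = exp(log_rr), corrected = corrected,
                excluded = FALSE, reason = reason)
  }
  class(est) <- "effect_estimate"
  est
}

#' DerSimonian-Laird between-study variance
#'
#' Moment estimator: with fixed-effect inverse-variance weights
#' `w = 1/v`, `Q = sum(w * (y - yhat)^2)` around the fixed-effect mean,
#' and `tau2 = max(0, (Q - (k - 1)) / (sum(w) - sum(w^2)/sum(w)))`.
#'
#' @param log_rr numeric vector of study log relative risks.
#' @param var_log_rr numeric vector of their variances.
#' @return list with `tau2`, `q`, `k`.
#' @export
dl_tau_squared <- function(log_rr, var_log_rr) {
  stopifnot(length(log_rr) == length(var_log_rr), length(log_rr) >= 1,
            all(var_log_rr > 0))
  k <- length(log_rr)
  if (k == 1L) return(list(tau2 = 0, q = 0, k = 1L))
  w <- 1 / var_log_rr
  y_fixed <- sum(w * log_rr) / sum(w)
  q <- sum(w * (log_rr - y_fixed)^2)
  denom <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (q - (k - 1)) / denom)
  list(tau2 = tau2, q = q, k = k)
}

#' Pool effect estimates with DerSimonian-Laird random effects
#'
#' Random-effects weights are `1/(v + tau2)`; the 95% confidence interval
#' uses the normal multiplier 1.96 and the p-value the two-sided standard
#' normal tail of `z = pooled / SE`.
#'
#' @param estimates a list of [effect_from_table()] results (excluded
#'   entries are dropped), or a data.frame with columns `log_rr` and
#'   `var_log_rr`.
#' @param ci_multiplier normal quantile for the interval (1.96).
#' @return A list of class `pooled_result`: `rr`, `ci_low`, `ci_high`,
#'   `z`, `p`, `tau2`, `q`, `k`, `log_rr`, `se_log_rr`.
#' @export
pool_random_effects <- function(estimates, ci_multiplier = 1.96) {
  if (is.data.frame(estimates)) {
    y <- estimates$log_rr
    v <- estimates$var_log_rr
  } else {
    if (inherits(estimates, "effect_estimate")) estimates <- list(estimates)
    keep <- !vapply(estimates, function(e) isTRUE(e$excluded), logical(1))
    y <- vapply(estimates[keep], function(e) e$log_rr, numeric(1))
    v <- vapply(estimates[keep], function(e) e$var_log_rr, numeric(1))
  }
  if (length(y) == 0L)
    stop("no poolable estimates (all excluded or empty input)", call. = FALSE)
  ht <- dl_tau_squared(y, v)
  w <- 1 / (v + ht$tau2)
  mu <- sum(w * y) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- mu / se
  out <- list(rr = exp(mu),
              ci_low = exp(mu - ci_multiplier * se),
              ci_high = exp(mu + ci_multiplier * se),
              z = z,
              p = 2 * stats::pnorm(-abs(z)),
              tau2 = ht$tau2, q = ht$q, k = ht$k,
              log_rr = mu, se_log_rr = se)
  class(out) <- "pooled_result"
  out
}

#' Mantel-Haenszel fixed-effect pooled relative risk
#'
#' Cross-check estimator: `RR = sum(a * n2 / N) / sum(c * n1 / N)` with the
#' Greenland-Robins variance for the log relative risk. No continuity
#' correction is needed; double-zero tables contribute nothing and are
#' dropped.
#'
#' @param events_a,total_a,events_b,total_b integer vectors, one entry per
#'   study.
#' @inheritParams pool_random_effects
#' @return A `pooled_result` (with `tau2 = 0` and `q = NA`).
#' @export
pool_mantel_haenszel <- function(events_a, total_a, events_b, total_b,
                                 ci_multiplier = 1.96) {
  keep <- !(events_a == 0 & events_b == 0)
  a <- events_a[keep]; n1 <- total_a[keep]
  c <- events_b[keep]; n2 <- total_b[keep]
  if (length(a) == 0L)
    stop("no poolable tables (all double-zero)", call. = FALSE)
  N <- n1 + n2
  R <- sum(a * n2 / N)
  S <- sum(c * n1 / N)
  mu <- log(R / S)
  var_mu <- sum((n1 * n2 * (a + c) - a * c * N) / N^2) / (R * S)
  se <- sqrt(var_mu)
  z <- mu / se
  out <- list(rr = exp(mu),
              ci_low = exp(mu - ci_multiplier * se),
              ci_high = exp(mu + ci_multiplier * se),
              z = z,
              p = 2 * stats::pnorm(-abs(z)),
              tau2 = 0, q = NA_real_, k = length(a),
              log_rr = mu, se_log_rr = se)
  class(out) <- "pooled_result"
  out
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf("RR %.2f (95%% CI %.2f, %.2f), p = %s; tau2 = %.3f, k = %d\n",
              x$rr, x$ci_low, x$ci_high, format.pval(x$p, digits = 2),
              x$tau2, x$k))
  invisible(x)
}

# Assemble the 2x2 tables one review contributes for one outcome at one
# timepoint. Units with an unspecified timepoint contribute their single
# dataset to every timepoint.
assemble_tables <- function(corpus, review_id, outcome_id,
                            timepoint = "unspecified",
                            exclude_units = character()) {
  rows <- do.call(rbind, Filter(Negate(is.null), lapply(
    setdiff(corpus$study_units$unit_id, exclude_units),
    function(u) analysed_row(corpus, review_id, u, outcome_id,
                             if (timepoint == "unspecified") "as_analysed"
                             else timepoint))))
  rows
}

#' Pooled relative risk from one review's extracted data
#'
#' Assembles a 2x2 table per study unit the review analysed for the
#' outcome (selecting the requested timepoint for units reported at
#' several), applies [effect_from_table()] and pools with
#' [pool_random_effects()] (or the Mantel-Haenszel fixed-effect
#' cross-check).
#'
#' @inheritParams audit_outcome
#' @param timepoint `"unspecified"`, `"one_year"` or `"thirteen_year"`.
#' @param exclude_units study units to leave out of this pool (sensitivity
#'   exclusions).
#' @param estimator `"dl"` (DerSimonian-Laird inverse-variance random
#'   effects, the default) or `"mh_fixed"`.
#' @param correction continuity policy, see [effect_from_table()].
#' @return A `pooled_result` with attributes `review_id`, `outcome_id`,
#'   `timepoint`, `units` (pooled units) and `excluded` (double-zero or
#'   explicitly excluded units).
#' @export
pooled_from_corpus <- function(corpus, review_id, outcome_id,
                               timepoint = c("unspecified", "one_year",
                                             "thirteen_year"),
                               exclude_units = character(),
                               estimator = c("dl", "mh_fixed"),
                               correction = "half") {
  stopifnot(inherits(corpus, "audit_corpus"))
  timepoint <- match.arg(timepoint)
  estimator <- match.arg(estimator)
  rows <- assemble_tables(corpus, review_id, outcome_id, timepoint,
                          exclude_units)
  if (is.null(rows) || nrow(rows) == 0L)
    stop(sprintf("no analysable studies for %s/%s at %s", review_id,
                 outcome_id, timepoint), call. = FALSE)
  ests <- lapply(seq_len(nrow(rows)), function(i)
    effect_from_table(rows$arm_a_events[i], rows$arm_a_total[i],
                      rows$arm_b_events[i], rows$arm_b_total[i],
                      correction = correction))
  kept <- !vapply(ests, `[[`, logical(1), "excluded")
  if (!any(kept))
    stop(sprintf("no analysable studies for %s/%s at %s (all excluded)",
                 review_id, outcome_id, timepoint), call. = FALSE)
  res <- if (estimator == "dl") {
    pool_random_effects(ests)
  } else {
    pool_mantel_haenszel(rows$arm_a_events, rows$arm_a_total,
                         rows$arm_b_events, rows$arm_b_total)
  }
  attr(res, "review_id") <- review_id
  attr(res, "outcome_id") <- outcome_id
  attr(res, "timepoint") <- timepoint
  attr(res, "units") <- rows$study_unit_id[kept]
  attr(res, "excluded") <- c(rows$study_unit_id[!kept], exclude_units)
  res
}

# Timepoints at which a review x outcome is poolable: the explicit
# timepoints of its reported rows, or "unspecified" when it only reports
# untimed rows.
available_timepoints <- function(corpus, review_id, outcome_id) {
  rows <- review_rows(corpus, review_id, outcome_id)
  if (nrow(rows) == 0L) return(character())
  tp <- setdiff(unique(rows$timepoint), "unspecified")
  if (length(tp) == 0L) "unspecified" else tp[order(match(tp, TIMEPOINTS))]
}

#' Pooled-result grid across reviews, outcomes and timepoints
#'
#' Recomputes the pooled relative risk for every review x outcome cell
#' that has analysable data, at each timepoint the review reported.
#'
#' @inheritParams audit_outcome
#' @param exclusions optional data.frame with columns `review_id`,
#'   `outcome_id`, `timepoint`, `study_unit_id` naming study units to drop
#'   from specific pools (see [fixture_meta_exclusions()]).
#' @param estimator,correction passed to [pooled_from_corpus()].
#' @return data.frame with one row per pooled cell: `review_id`,
#'   `outcome_id`, `timepoint`, `k`, `rr`, `ci_low`, `ci_high`, `z`, `p`,
#'   `tau2`, `significant`.
#' @export
meta_table <- function(corpus, exclusions = NULL, estimator = "dl",
                       correction = "half") {
  stopifnot(inherits(corpus, "audit_corpus"))
  out <- list()
  for (review in corpus$reviews) {
    for (outcome in OUTCOMES) {
      for (tp in available_timepoints(corpus, review, outcome)) {
        excl <- character()
        if (!is.null(exclusions)) {
          m <- exclusions$review_id == review &
            exclusions$outcome_id == outcome & exclusions$timepoint == tp
          excl <- exclusions$study_unit_id[m]
        }
        res <- tryCatch(
          pooled_from_corpus(corpus, review, outcome, timepoint = tp,
                             exclude_units = excl, estimator = estimator,
                             correction = correction),
          error = function(e) NULL)
        if (is.null(res)) next
        out[[length(out) + 1L]] <- data.frame(
          review_id = review, outcome_id = outcome, timepoint = tp,
          k = res$k, rr = res$rr, ci_low = res$ci_low,
          ci_high = res$ci_high, z = res$z, p = res$p, tau2 = res$tau2,
          significant = res$ci_low > 1 | res$ci_high < 1,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Study-unit exclusions used to reproduce the published pooled grid
#'
#' The published pooled analysis of the revision outcome from the Cochrane
#' extraction omits the Blomfeldt trial: the single revision event the
#' Cochrane review counted there was a wound revision rather than a
#' revision of the implant (see the corpus annotations), leaving no
#' implant-revision events in either arm. With the trial included the
#' pooled RR is 0.45 (0.21, 0.98) instead of the published 0.40
#' (0.18, 0.89); all other cells of the grid need no exclusion.
#'
#' @return data.frame in the layout accepted by `meta_table(exclusions=)`.
#' @export
fixture_meta_exclusions <- function() {
  data.frame(review_id = "Cochrane", outcome_id = "revision",
             timepoint = "one_year", study_unit_id = "blomfeldt_2007",
             stringsAsFactors = FALSE)
}

#' Forest plot of one pooled analysis
#'
#' Draws per-study relative risks with 95% intervals and the pooled
#' diamond on a log axis, base graphics.
#'
#' @param corpus,review_id,outcome_id,timepoint,exclude_units,correction
#'   as in [pooled_from_corpus()].
#' @return The `pooled_result`, invisibly.
#' @export
forest_plot <- function(corpus, review_id, outcome_id,
                        timepoint = "unspecified",
                        exclude_units = character(), correction = "half") {
  rows <- assemble_tables(corpus, review_id, outcome_id, timepoint,
                          exclude_units)
  ests <- lapply(seq_len(nrow(rows)), function(i)
    effect_from_table(rows$arm_a_events[i], rows$arm_a_total[i],
                      rows$arm_b_events[i], rows$arm_b_total[i],
                      correction = correction))
  keep <- !vapply(ests, `[[`, logical(1), "excluded")
  pooled <- pool_random_effects(ests)
  y <- vapply(ests[keep], `[[`, numeric(1), "log_rr")
  se <- sqrt(vapply(ests[keep], `[[`, numeric(1), "var_log_rr"))
  labs <- rows$study_unit_id[keep]
  k <- length(y)
  xlim <- range(c(exp(y - 1.96 * se), exp(y + 1.96 * se),
                  pooled$ci_low, pooled$ci_high, 1))
  plot(NA, xlim = xlim, ylim = c(0, k + 1), log = "x", yaxt = "n",
       xlab = "Relative risk (log scale)", ylab = "",
       main = sprintf("%s: %s (%s)", review_id, outcome_id, timepoint))
  graphics::axis(2, at = c(k:1, 0), labels = c(labs, "Pooled (DL)"),
                 las = 1, cex.axis = 0.8)
  graphics::abline(v = 1, lty = 2, col = "grey50")
  graphics::segments(exp(y - 1.96 * se), k:1, exp(y + 1.96 * se), k:1)
  graphics::points(exp(y), k:1, pch = 15)
  graphics::polygon(c(pooled$ci_low, pooled$rr, pooled$ci_high, pooled$rr),
                    c(0, 0.25, 0, -0.25), col = "grey30")
  invisible(pooled)
}
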