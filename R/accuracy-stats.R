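#' 2x2 confusion counts
#'
#' @param final_recalls,truths Aligned integer 0/1 vectors.
#' @return List of class `confusion_counts`: `tp`, `fp`, `fn`, `tn`, `n`.
#' @export
confusion_counts <- function(final_recalls, truths) {
  if (length(final_recalls) != length(truths))
    stop("final_recalls and truths must have equal length")
  tp <- sum(final_recalls == 1L & truths == 1L)
  fp <- sum(final_recalls == 1L & truths == 0L)
  fn <- sum(final_recalls == 0L & truths == 1L)
  tn <- sum(final_recalls == 0L & truths == 0L)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, n = tp + fp + fn + tn),
            class = "confusion_counts")
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Beta-quantile form of the exact interval; the lower bound is 0 at zero
#' successes and the upper bound 1 at `n` successes.
#'
#' @param successes,n Counts with `0 <= successes <= n`, `n > 0`.
#' @param level Confidence level, default 0.95.
#' @return Numeric `c(lower, upper)`.
#' @export
clopper_pearson <- function(successes, n, level = 0.95) {
  if (n <= 0 || successes < 0 || successes > n)
    stop("require 0 <= successes <= n with n > 0")
  alpha <- 1 - level
  lower <- if (successes == 0) 0 else
    stats::qbeta(alpha / 2, successes, n - successes + 1)
  upper <- if (successes == n) 1 else
    stats::qbeta(1 - alpha / 2, successes + 1, n - successes)
  c(lower = lower, upper = upper)
}

# proportion + exact CI as a small record; NA-flagged when undefined
prop_ci <- function(successes, n, level) {
  if (n == 0)
    return(list(estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                successes = successes, n = n, defined = FALSE))
  ci <- clopper_pearson(successes, n, level)
  list(estimate = successes / n, lower = ci[["lower"]], upper = ci[["upper"]],
       successes = successes, n = n, defined = TRUE)
}

#' Per-scenario accuracy summary
#'
#' Sensitivity, specificity, PPV, NPV, recall rate, and arbitration rate
#' (each with exact Clopper-Pearson CIs), the cancer detection rate per 1000
#' screens, and the single-operating-point AUC. Metrics with a zero
#' denominator come back NA with `defined = FALSE` rather than failing.
#'
#' @param counts A [confusion_counts()] object.
#' @param arbitration_flags Logical vector: was an arbitration read used.
#' @param level Confidence level for the CIs.
#' @return List of class `accuracy_summary`.
#' @export
accuracy_summary <- function(counts, arbitration_flags, level = 0.95) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$n == 0) stop("accuracy_summary requires n > 0")
  with(counts, {
    sens <- prop_ci(tp, tp + fn, level)
    spec <- prop_ci(tn, tn + fp, level)
    structure(list(
      sensitivity = sens,
      specificity = spec,
      ppv = prop_ci(tp, tp + fp, level),
      npv = prop_ci(tn, tn + fn, level),
      recall_rate = prop_ci(tp + fp, n, level),
      arbitration_rate = prop_ci(sum(arbitration_flags),
                                 length(arbitration_flags), level),
      cdr_per_1000 = 1000 * tp / n,
      auc = operating_point_auc(sens$estimate, spec$estimate),
      counts = counts, level = level),
      class = "accuracy_summary")
  })
}

#' @export
print.accuracy_summary <- function(x, ...) {
  fmt <- function(nm, m, scale = 100, unit = "%") {
    if (!m$defined) return(cat(sprintf("  %-17s undefined (0 denominator)\n", nm)))
    cat(sprintf("  %-17s %6.2f%s  (%5.2f-%5.2f)  [%d/%d]\n", nm,
                scale * m$estimate, unit, scale * m$lower, scale * m$upper,
                m$successes, m$n))
  }
  cat("Screening accuracy summary:\n")
  fmt("sensitivity", x$sensitivity); fmt("specificity", x$specificity)
  fmt("PPV", x$ppv); fmt("NPV", x$npv)
  fmt("recall rate", x$recall_rate); fmt("arbitration rate", x$arbitration_rate)
  cat(sprintf("  %-17s %6.2f per 1000\n", "CDR", x$cdr_per_1000))
  cat(sprintf("  %-17s %6.3f\n", "AUC (one point)", x$auc))
  invisible(x)
}

#' McNemar test for paired binary outcomes
#'
#' Adaptive form: with `b + c` at or above `exact_cutoff` discordant pairs,
#' the chi-square statistic `(b - c)^2 / (b + c)` on 1 df without continuity
#' correction; below the cutoff, the exact two-sided binomial test of
#' `b ~ Binomial(b + c, 1/2)`. With no discordant pairs at all, p = 1.
#'
#' @param b,c Discordant-pair counts.
#' @param exact_cutoff Discordant total below which the exact branch is
#'   used; default 25.
#' @return List with `statistic` (NA on the exact branch), `p_value`,
#'   `b`, `c`, and `method`.
#' @export
mcnemar_test <- function(b, c, exact_cutoff = 25) {
  if (b < 0 || c < 0) stop("discordant counts must be nonnegative")
  nd <- b + c
  if (nd == 0)
    return(list(statistic = 0, p_value = 1, b = b, c = c, method = "none"))
  if (nd < exact_cutoff) {
    p <- min(1, 2 * stats::pbinom(min(b, c), nd, 0.5))
    return(list(statistic = NA_real_, p_value = p, b = b, c = c,
                method = "exact"))
  }
  stat <- (b - c)^2 / nd
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       b = b, c = c, method = "asymptotic")
}

#' Generalized score test for paired predictive values
#'
#' Compares the PPV (or NPV) of two screening decisions made on the same
#' exams. The positive (or negative) calls of both arms are stacked into one
#' record set; under the null the outcome probability is common across arms,
#' and the score for the arm effect is standardized by an empirical sandwich
#' variance clustered on the exam, which respects the pairing. The statistic
#' is asymptotically chi-square on 1 df.
#'
#' @param truths Integer 0/1 truth labels.
#' @param recalls_a,recalls_b Aligned 0/1 decisions for the two arms
#'   (convention: a = comparator, b = scenario).
#' @param which `"ppv"` or `"npv"`.
#' @return List with `statistic`, `p_value`, the two predictive values
#'   `pv_a`, `pv_b`, and the record counts `n_a`, `n_b`.
#' @export
paired_pv_score_test <- function(truths, recalls_a, recalls_b,
                                 which = c("ppv", "npv")) {
  which <- match.arg(which)
  stopifnot(length(truths) == length(recalls_a),
            length(truths) == length(recalls_b))
  if (which == "ppv") {
    in_a <- recalls_a == 1L; in_b <- recalls_b == 1L
    outcome <- truths               # P(cancer | recall)
  } else {
    in_a <- recalls_a == 0L; in_b <- recalls_b == 0L
    outcome <- 1L - truths          # P(no cancer | no recall)
  }
  n_a <- sum(in_a); n_b <- sum(in_b)
  if (n_a == 0L) stop("arm a has no ", if (which == "ppv") "positive" else
                      "negative", " calls")
  if (n_b == 0L) stop("arm b has no ", if (which == "ppv") "positive" else
                      "negative", " calls")
  id <- c(which(in_a), which(in_b))
  x <- c(rep(0, n_a), rep(1, n_b))
  y <- outcome[id]
  xbar <- mean(x); ybar <- mean(y)
  resid <- (x - xbar) * (y - ybar)
  u <- sum(resid)
  v <- sum(as.vector(rowsum(resid, id))^2)
  pv_a <- mean(outcome[in_a]); pv_b <- mean(outcome[in_b])
  if (v <= 0 || u^2 / v < .Machine$double.eps)
    return(list(statistic = 0, p_value = 1, pv_a = pv_a, pv_b = pv_b,
                n_a = n_a, n_b = n_b))
  stat <- u^2 / v
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       pv_a = pv_a, pv_b = pv_b, n_a = n_a, n_b = n_b)
}

#' AUC of a single binary operating point
#'
#' Trapezoidal area of the ROC polygon through (0,0), (1-spec, sens), (1,1):
#' `(sens + spec) / 2`.
#'
#' @param sens,spec Probabilities in `[0, 1]`.
#' @return AUC in `[0, 1]`.
#' @export
operating_point_auc <- function(sens, spec) {
  if (any(c(sens, spec) < 0 | c(sens, spec) > 1, na.rm = TRUE))
    stop("sens and spec must lie in [0, 1]")
  (sens + spec) / 2
}

#' Empirical AUC of a continuous score
#'
#' Rank-based Mann-Whitney statistic, counting ties as one half.
#'
#' @param scores Numeric scores (higher = more suspicious).
#' @param truths Integer 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
empirical_auc <- function(scores, truths) {
  stopifnot(length(scores) == length(truths))
  n1 <- sum(truths == 1L); n0 <- sum(truths == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("empirical AUC requires both classes present")
  r <- rank(scores)
  (sum(r[truths == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Welch two-sample t test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' (wraps [stats::t.test()]).
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @return List with `statistic`, `p_value`, `df`, and the two means.
#' @export
welch_t_test <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each group needs at least 2 observations")
  tt <- stats::t.test(values_a, values_b, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter),
       mean_a = mean(values_a), mean_b = mean(values_b))
}

#' Paired scenario-vs-combined endpoint comparisons
#'
#' Sensitivity and specificity (coprimary endpoints) are compared by McNemar
#' tests on the cancer and non-cancer strata; recall rate and arbitration
#' rate by McNemar over all exams; PPV and NPV by the generalized score test
#' for paired predictive values. Deltas are scenario minus combined, in
#' percentage points.
#'
#' @param cohort A cohort data frame (provides `truth`).
#' @param outcomes_scenario,outcomes_combined Aligned `scenario_outcome`
#'   data frames.
#' @param alpha_coprimary Significance level for sensitivity/specificity
#'   (default 0.05/6 = 0.00833, Bonferroni across 2 coprimary endpoints x
#'   3 scenarios).
#' @param alpha_secondary Significance level for the other endpoints.
#' @param exact_cutoff Passed to [mcnemar_test()].
#' @return Data frame of class `paired_comparison` with one row per
#'   endpoint: `endpoint`, `delta_pp`, `statistic`, `p_value`, `b`, `c`,
#'   `alpha`, `significant`.
#' @export
compare_scenarios <- function(cohort, outcomes_scenario, outcomes_combined,
                              alpha_coprimary = 0.05 / 6,
                              alpha_secondary = 0.05,
                              exact_cutoff = 25) {
  stopifnot(nrow(outcomes_scenario) == nrow(cohort),
            nrow(outcomes_combined) == nrow(cohort),
            all(outcomes_scenario$exam_id == cohort$exam_id),
            all(outcomes_combined$exam_id == cohort$exam_id))
  s <- outcomes_scenario$final_recall
  k <- outcomes_combined$final_recall
  truth <- cohort$truth

  mcnemar_row <- function(endpoint, sel, s_pos, k_pos, alpha) {
    b <- sum(sel & s_pos & !k_pos)   # scenario "yes", combined "no"
    c <- sum(sel & !s_pos & k_pos)
    m <- mcnemar_test(b, c, exact_cutoff)
    delta <- 100 * (b - c) / sum(sel)
    data.frame(endpoint = endpoint, delta_pp = delta,
               statistic = if (is.na(m$statistic)) NA_real_ else m$statistic,
               p_value = m$p_value, b = b, c = c, alpha = alpha,
               significant = m$p_value < alpha)
  }
  pv_row <- function(endpoint, which, alpha) {
    t <- paired_pv_score_test(truth, k, s, which)
    data.frame(endpoint = endpoint, delta_pp = 100 * (t$pv_b - t$pv_a),
               statistic = t$statistic, p_value = t$p_value,
               b = NA_integer_, c = NA_integer_, alpha = alpha,
               significant = t$p_value < alpha)
  }
  arb_s <- outcomes_scenario$arbitration_used
  arb_k <- outcomes_combined$arbitration_used
  out <- rbind(
    mcnemar_row("sensitivity", truth == 1L, s == 1L, k == 1L, alpha_coprimary),
    mcnemar_row("specificity", truth == 0L, s == 0L, k == 0L, alpha_coprimary),
    pv_row("ppv", "ppv", alpha_secondary),
    pv_row("npv", "npv", alpha_secondary),
    mcnemar_row("recall_rate", rep(TRUE, length(s)), s == 1L, k == 1L,
                alpha_secondary),
    mcnemar_row("arbitration_rate", rep(TRUE, length(s)), arb_s, arb_k,
                alpha_secondary))
  class(out) <- c("paired_comparison", "data.frame")
  out
}

#' Sensitivity restricted to a cancer subgroup
#'
#' @param outcomes A `scenario_outcome` data frame.
#' @param cohort The aligned cohort (provides `truth` and `subgroup`).
#' @param subgroup `"screen_detected"` or `"interval"`.
#' @param level Confidence level for the Clopper-Pearson CI.
#' @return A proportion record (see [accuracy_summary()]); `defined = FALSE`
#'   when the subgroup is empty.
#' @export
subgroup_sensitivity <- function(outcomes, cohort,
                                 subgroup = c("screen_detected", "interval"),
                                 level = 0.95) {
  subgroup <- match.arg(subgroup)
  stopifnot(all(outcomes$exam_id == cohort$exam_id))
  sel <- cohort$truth == 1L & cohort$subgroup == subgroup
  prop_ci(sum(outcomes$final_recall[sel] == 1L), sum(sel), level)
}
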