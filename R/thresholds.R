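#' AI threshold matched at a target specificity
#'
#' Under the strict recall rule (`score > threshold`), the specificity
#' achieved by a cutoff `t` is the fraction of non-cancer scores `<= t`.
#' Returns the smallest observed score value whose empirical specificity
#' reaches the target; the realized specificity can exceed the target when
#' ties make the target unattainable exactly.
#'
#' @param noncancer_scores Non-empty numeric vector of non-cancer AI scores.
#' @param target_spec Target specificity in `[0, 1]`.
#' @return List with `threshold` and `realized_specificity`.
#' @examples
#' threshold_at_specificity(1:10, 0.8)  # threshold 8, realized 0.8
#' @export
threshold_at_specificity <- function(noncancer_scores, target_spec) {
  if (length(noncancer_scores) == 0L)
    stop("threshold_at_specificity requires at least one non-cancer score")
  if (target_spec < 0 || target_spec > 1)
    stop("target_spec must lie in [0, 1]")
  u <- sort(unique(noncancer_scores))
  cum <- cumsum(tabulate(match(sort(noncancer_scores), u), length(u)))
  frac <- cum / length(noncancer_scores)
  i <- which(frac >= target_spec)[1]
  list(threshold = u[i], realized_specificity = frac[i])
}

#' Dual-constraint triage threshold search
#'
#' Selects the (low, high) AI-score pair for the triage workflow: the
#' moderate-risk band `[low, high)` should hold `moderate_target` of all
#' screenings while the triage recall rate matches `recall_target`
#' (by default the combined reading's own recall rate, so triage does not
#' inflate recalls).
#'
#' Candidate cutoffs are the unique observed scores plus one sentinel above
#' the maximum (an empty high band). For every high candidate the low
#' candidate bringing the moderate fraction nearest the target is paired
#' with it; among these pairs the one minimizing the absolute recall-rate
#' gap wins, with ties broken by the moderate-fraction gap and then by the
#' smaller high cutoff.
#'
#' @param cohort A cohort data frame with `ai_score`.
#' @param combined A `scenario_outcome` from [combined_reading()] aligned
#'   with `cohort`.
#' @param moderate_target Desired moderate-band fraction in `(0, 1]`.
#' @param recall_target Desired triage recall rate; default is the combined
#'   reading's recall rate.
#' @return An object of class `triage_thresholds`: `triage_low`,
#'   `triage_high`, `realized_moderate_fraction`, `realized_recall_rate`,
#'   `recall_target`, `moderate_target`.
#' @export
select_triage_thresholds <- function(cohort, combined,
                                     moderate_target = 0.5,
                                     recall_target = NULL) {
  stopifnot(nrow(combined) == nrow(cohort),
            all(combined$exam_id == cohort$exam_id))
  if (moderate_target <= 0 || moderate_target > 1)
    stop("moderate_target must lie in (0, 1]")
  n <- nrow(cohort)
  if (is.null(recall_target)) recall_target <- mean(combined$final_recall)

  ord <- order(cohort$ai_score)
  s <- cohort$ai_score[ord]
  rec <- combined$final_recall[ord]
  u <- unique(s)
  k <- length(u)
  # below[j]  = #{score <  u[j]};  recall_below[j] parallel for combined recalls
  cnt <- tabulate(match(s, u), k)
  rec_cnt <- as.vector(rowsum(rec, match(s, u)))
  below <- c(0, cumsum(cnt))[seq_len(k)]
  rec_below <- c(0, cumsum(rec_cnt))[seq_len(k)]
  # candidates include a sentinel above the max (empty high band)
  cand <- c(u, u[k] + 1)
  below <- c(below, n)
  rec_below <- c(rec_below, sum(rec))

  # for each high candidate h (index a): high count = n - below[a];
  # want below[b] for the low candidate nearest below[a] - n*target
  want <- below - n * moderate_target
  # nearest value in the nondecreasing vector `below`, restricted to b < a
  bi <- findInterval(want, below)           # largest index with below[] <= want
  pick_nearer <- function(a, i) {
    # compare below[i] and below[i+1] against want[a]; clamp to [1, a-1]
    lo <- max(1L, min(i, a - 1L))
    hi <- max(1L, min(i + 1L, a - 1L))
    if (abs(below[hi] - want[a]) < abs(below[lo] - want[a])) hi else lo
  }
  a_idx <- which(seq_along(cand) >= 2)      # need at least one low candidate below
  b_idx <- vapply(a_idx, function(a) pick_nearer(a, bi[a]), integer(1))

  mod_frac <- (below[a_idx] - below[b_idx]) / n
  recall_rate <- ((n - below[a_idx]) +                      # high band auto-recall
                  (rec_below[a_idx] - rec_below[b_idx])) / n  # combined in moderate
  gap_recall <- abs(recall_rate - recall_target)
  gap_mod <- abs(mod_frac - moderate_target)
  best <- order(gap_recall, gap_mod, cand[a_idx])[1]
  if (!length(best)) stop("no feasible (low, high) pair with low < high")

  structure(list(triage_low = cand[b_idx[best]],
                 triage_high = cand[a_idx[best]],
                 realized_moderate_fraction = mod_frac[best],
                 realized_recall_rate = recall_rate[best],
                 recall_target = recall_target,
                 moderate_target = moderate_target),
            class = "triage_thresholds")
}

#' @export
print.triage_thresholds <- function(x, ...) {
  cat(sprintf(paste0("Triage thresholds: low %.4g, high %.4g\n",
                     "  moderate fraction %.4f (target %.4f)\n",
                     "  recall rate %.5f (target %.5f)\n"),
              x$triage_low, x$triage_high,
              x$realized_moderate_fraction, x$moderate_target,
              x$realized_recall_rate, x$recall_target))
  invisible(x)
}
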