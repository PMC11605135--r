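#' Dichotomize an AI score
#'
#' An exam is an AI recall when its score lies strictly above the threshold
#' (scores exactly at the threshold are not recalled).
#'
#' @param score Numeric score(s) in `[0, 100]`.
#' @param threshold Single cutoff in `[0, 100]`.
#' @return Integer 0/1 recall decision(s).
#' @examples
#' dichotomize_ai(81.0, 80.99)   # 1
#' dichotomize_ai(80.99, 80.99)  # 0
#' @export
dichotomize_ai <- function(score, threshold) {
  if (any(score < 0 | score > 100) || threshold < 0 || threshold > 100)
    stop("scores and threshold must lie in [0, 100]")
  as.integer(score > threshold)
}

scenario_levels <- c("combined", "ai_first", "ai_second", "ai_triage")

new_scenario_outcome <- function(exam_id, scenario, final_recall, human_reads,
                                 arbitration_used, arbitration_source) {
  out <- data.frame(exam_id = exam_id,
                    scenario = scenario,
                    final_recall = as.integer(final_recall),
                    human_reads = as.integer(human_reads),
                    arbitration_used = arbitration_used,
                    arbitration_source = arbitration_source)
  class(out) <- c("scenario_outcome", "data.frame")
  out
}

#' Standard combined double reading with arbitration
#'
#' Both readers read every exam. If they agree, their shared decision is
#' final (2 human reads). If they disagree, the original arbitration decides
#' (3 human reads). A disagreement without an arbitration decision violates
#' the cohort contract and is an error.
#'
#' @param cohort A cohort data frame (see [generate_cohort()]).
#' @return A `scenario_outcome` data frame (one row per exam) with columns
#'   `exam_id`, `scenario`, `final_recall`, `human_reads`,
#'   `arbitration_used`, `arbitration_source`.
#' @export
combined_reading <- function(cohort) {
  disagree <- cohort$reader1 != cohort$reader2
  if (any(disagree & is.na(cohort$arbitration)))
    stop("combined reading requires an arbitration for every disagreement")
  final <- ifelse(disagree, cohort$arbitration, cohort$reader1)
  new_scenario_outcome(cohort$exam_id, "combined", final,
                       ifelse(disagree, 3L, 2L), disagree,
                       ifelse(disagree, "original", "none"))
}

#' Estimate the original arbitrator's operating point
#'
#' Computed on the arbitrated exams only: sensitivity is the fraction of
#' arbitrated cancers given a recall, specificity the fraction of arbitrated
#' non-cancers given no recall. Both strata must be non-empty; otherwise the
#' caller must supply an `arbitrator_profile()` explicitly.
#'
#' @param cohort A cohort data frame.
#' @return An `arbitrator_profile` object with `sens`, `spec`,
#'   `n_cancer_est`, `n_noncancer_est`.
#' @export
estimate_arbitrator_profile <- function(cohort) {
  arb <- cohort[!is.na(cohort$arbitration), , drop = FALSE]
  n_ca <- sum(arb$truth == 1L)
  n_nc <- sum(arb$truth == 0L)
  if (n_ca == 0L || n_nc == 0L)
    stop("cannot estimate the arbitrator profile: no arbitrated ",
         if (n_ca == 0L) "cancers" else "non-cancers",
         "; supply an arbitrator_profile() explicitly")
  arbitrator_profile(
    sens = sum(arb$arbitration == 1L & arb$truth == 1L) / n_ca,
    spec = sum(arb$arbitration == 0L & arb$truth == 0L) / n_nc,
    n_cancer_est = n_ca, n_noncancer_est = n_nc)
}

#' Arbitrator accuracy profile
#'
#' Accuracy level at which new (simulated) arbitrations are drawn when an
#' AI-reader disagreement has no original arbitration to reuse.
#'
#' @param sens,spec Probabilities in `[0, 1]`.
#' @param n_cancer_est,n_noncancer_est Counts the estimates rest on
#'   (0 when the profile was supplied rather than estimated).
#' @return An `arbitrator_profile` object.
#' @export
arbitrator_profile <- function(sens, spec,
                               n_cancer_est = 0L, n_noncancer_est = 0L) {
  if (sens < 0 || sens > 1 || spec < 0 || spec > 1)
    stop("arbitrator sens/spec must lie in [0, 1]")
  structure(list(sens = sens, spec = spec,
                 n_cancer_est = as.integer(n_cancer_est),
                 n_noncancer_est = as.integer(n_noncancer_est)),
            class = "arbitrator_profile")
}

#' @export
print.arbitrator_profile <- function(x, ...) {
  cat(sprintf("Arbitrator profile: sens %.3f (n=%d), spec %.3f (n=%d)\n",
              x$sens, x$n_cancer_est, x$spec, x$n_noncancer_est))
  invisible(x)
}

#' Simulate an arbitration decision
#'
#' Draws a recall with probability `profile$sens` for cancers and
#' `1 - profile$spec` for non-cancers; the simulated arbitrator matches the
#' original arbitrator's accuracy level but conditions on truth only.
#' Uses the current RNG stream.
#'
#' @param truth Integer 0/1 truth labels.
#' @param profile An [arbitrator_profile()].
#' @return Integer 0/1 recall decision(s).
#' @export
simulate_arbitration <- function(truth, profile) {
  stopifnot(inherits(profile, "arbitrator_profile"))
  p <- ifelse(truth == 1L, profile$sens, 1 - profile$spec)
  as.integer(stats::runif(length(truth)) < p)
}

#' AI replaces the first or second reader
#'
#' The AI decision is paired with the retained human reader. Agreement makes
#' that decision final with a single human read; original arbitrations are
#' disregarded in that case. On disagreement the original arbitration is
#' reused when present (the original readers also disagreed); otherwise an
#' arbitration is simulated from `profile`. Either way the exam costs two
#' human reads (retained reader + arbitrator).
#'
#' @param cohort A cohort data frame.
#' @param ai_recall Integer 0/1 AI decisions, aligned with `cohort` (see
#'   [dichotomize_ai()]).
#' @param replaced `"first"` or `"second"` -- which human reader the AI
#'   replaces.
#' @param profile An [arbitrator_profile()] for simulated arbitrations.
#' @param seed Optional integer; when given, seeds the simulated-arbitration
#'   stream so the scenario is individually reproducible.
#' @return A `scenario_outcome` data frame.
#' @export
scenario_reader_replacement <- function(cohort, ai_recall,
                                        replaced = c("first", "second"),
                                        profile, seed = NULL) {
  replaced <- match.arg(replaced)
  stopifnot(length(ai_recall) == nrow(cohort))
  if (!is.null(seed)) set.seed(seed)
  retained <- if (replaced == "first") cohort$reader2 else cohort$reader1
  scenario <- if (replaced == "first") "ai_first" else "ai_second"

  disagree <- ai_recall != retained
  has_orig <- !is.na(cohort$arbitration)

  final <- ifelse(disagree, NA_integer_, retained)
  source <- rep("none", nrow(cohort))
  reuse <- disagree & has_orig
  final[reuse] <- cohort$arbitration[reuse]
  source[reuse] <- "original"
  sim <- disagree & !has_orig
  if (any(sim)) {
    final[sim] <- simulate_arbitration(cohort$truth[sim], profile)
    source[sim] <- "simulated"
  }
  new_scenario_outcome(cohort$exam_id, scenario, final,
                       ifelse(disagree, 2L, 1L), disagree, source)
}

#' Stand-alone AI triage into low / moderate / high risk
#'
#' Exams scoring at or above `high` are recalled with no human reads; exams
#' scoring below `low` are not recalled, also with no human reads; exams in
#' the moderate band `[low, high)` inherit the combined reading's decision,
#' reads, and arbitration provenance unchanged.
#'
#' @param cohort A cohort data frame.
#' @param low,high Band cutoffs in `[0, 100]` with `low < high` (`high` may
#'   sit above 100 as an "empty high band" sentinel).
#' @param combined A `scenario_outcome` from [combined_reading()], aligned
#'   with `cohort`.
#' @return A `scenario_outcome` data frame.
#' @export
scenario_triage <- function(cohort, low, high, combined) {
  if (low >= high) stop("triage requires low < high (got ", low, " >= ", high, ")")
  if (low < 0 || low > 100) stop("low threshold must lie in [0, 100]")
  stopifnot(nrow(combined) == nrow(cohort),
            all(combined$exam_id == cohort$exam_id))
  band <- triage_band(cohort$ai_score, low, high)
  is_high <- band == "high"
  is_low <- band == "low"
  mod <- band == "moderate"
  new_scenario_outcome(
    cohort$exam_id, "ai_triage",
    ifelse(is_high, 1L, ifelse(is_low, 0L, combined$final_recall)),
    ifelse(mod, combined$human_reads, 0L),
    mod & combined$arbitration_used,
    ifelse(mod, combined$arbitration_source, "none"))
}

#' Triage band membership
#'
#' @param score Numeric scores.
#' @param low,high Band cutoffs, `low < high`.
#' @return Character vector `"low"` (`score < low`), `"moderate"`
#'   (`low <= score < high`), or `"high"` (`score >= high`).
#' @export
triage_band <- function(score, low, high) {
  if (low >= high) stop("triage requires low < high")
  ifelse(score >= high, "high", ifelse(score < low, "low", "moderate"))
}

#' Workload accounting
#'
#' Totals human screen reads (arbitration reads count as one read each) for
#' a scenario and for the combined reading on the same exams and reports the
#' relative reduction.
#'
#' @param outcomes_scenario,outcomes_combined `scenario_outcome` data frames
#'   over the same exam set.
#' @return List with `total_reads_scenario`, `total_reads_combined`, and
#'   `relative_reduction` (percent; positive = fewer reads).
#' @export
tally_workload <- function(outcomes_scenario, outcomes_combined) {
  if (nrow(outcomes_scenario) != nrow(outcomes_combined) ||
      !setequal(outcomes_scenario$exam_id, outcomes_combined$exam_id))
    stop("workload comparison requires the same exam set in both arms")
  rs <- sum(outcomes_scenario$human_reads)
  rc <- sum(outcomes_combined$human_reads)
  list(total_reads_scenario = rs, total_reads_combined = rc,
       relative_reduction = 100 * (1 - rs / rc))
}

# fixed per-scenario RNG substream labels derived from one master seed,
# so each scenario is reproducible in isolation
scenario_seed <- function(seed, label) {
  offset <- c(cohort = 0L, ai_first = 1009L, ai_second = 2003L,
              ai_triage = 3001L, split = 4001L)[[label]]
  as.integer((as.numeric(seed) + offset) %% .Machine$integer.max)
}
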