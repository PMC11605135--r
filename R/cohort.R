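#' Draw correlated reader recall decisions
#'
#' Both readers threshold a shared bivariate standard-normal latent variable
#' (Gaussian copula) whose correlation depends on the truth class, so each
#' reader's marginal recall probability is exactly their sensitivity (for
#' cancers) or one minus their specificity (for non-cancers), while
#' within-exam agreement is governed by the dependence parameter.
#'
#' Uses the current RNG stream; callers control reproducibility with
#' `set.seed()` (the generator does this for you).
#'
#' @param truth Integer vector of truth labels (0/1).
#' @param params A [cohort_params()] object.
#' @return A two-column integer matrix with columns `reader1`, `reader2`.
#' @export
draw_reader_decisions <- function(truth, params) {
  n <- length(truth)
  rho <- ifelse(truth == 1,
                params$reader_dependence_cancer,
                params$reader_dependence_noncancer)
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  p1 <- ifelse(truth == 1, params$reader1_sens, 1 - params$reader1_spec)
  p2 <- ifelse(truth == 1, params$reader2_sens, 1 - params$reader2_spec)
  cbind(reader1 = as.integer(z1 <= stats::qnorm(p1)),
        reader2 = as.integer(z2 <= stats::qnorm(p2)))
}

#' Draw AI abnormality scores
#'
#' Samples the examination-level AI score (the maximum over both breasts in
#' a real system, modelled directly here) from the truth-conditional beta
#' mixture. Uses the current RNG stream.
#'
#' @inheritParams draw_reader_decisions
#' @return Numeric vector of scores in `[0, 100]`.
#' @export
draw_ai_score <- function(truth, params) {
  n <- length(truth)
  out <- numeric(n)
  ic <- truth == 1
  if (any(ic))  out[ic]  <- rmixture(sum(ic), params$ai_cancer_mixture)
  if (any(!ic)) out[!ic] <- rmixture(sum(!ic), params$ai_noncancer_mixture)
  out
}

#' Attach original arbitration decisions to reader disagreements
#'
#' Exams where the two readers disagree receive an arbitration decision,
#' drawn with probability `arbitrator_sens` of recall for cancers and
#' `1 - arbitrator_spec` for non-cancers. Exams where the readers agree get
#' `NA` (arbitration absent). Uses the current RNG stream.
#'
#' @param cohort A cohort data frame with `truth`, `reader1`, `reader2`.
#' @inheritParams draw_reader_decisions
#' @return The cohort with an `arbitration` column (integer 0/1 or `NA`).
#' @export
attach_original_arbitrations <- function(cohort, params) {
  disagree <- cohort$reader1 != cohort$reader2
  arb <- rep(NA_integer_, nrow(cohort))
  if (any(disagree)) {
    p <- ifelse(cohort$truth[disagree] == 1,
                params$arbitrator_sens, 1 - params$arbitrator_spec)
    arb[disagree] <- as.integer(stats::runif(sum(disagree)) < p)
  }
  cohort$arbitration <- arb
  cohort
}

# truncated-normal ages on the screening window
draw_ages <- function(n, mean, sd, range) {
  lo <- stats::pnorm(range[1], mean, sd)
  hi <- stats::pnorm(range[2], mean, sd)
  stats::qnorm(lo + stats::runif(n) * (hi - lo), mean, sd)
}

# woman ids: counts per woman are 1 + Poisson(mean - 1), truncated so the
# total matches n exactly; exams stay independent, the id is bookkeeping
draw_woman_ids <- function(n, exams_per_woman_mean) {
  counts <- 1L + stats::rpois(n, exams_per_woman_mean - 1)
  cum <- cumsum(counts)
  k <- which(cum >= n)[1]
  counts <- counts[seq_len(k)]
  counts[k] <- counts[k] - (cum[k] - n)
  rep.int(seq_len(k), counts)
}

#' Generate a synthetic screening cohort
#'
#' Produces one row per screening exam: truth label, AI score, both reader
#' decisions, the original arbitration (present iff the readers disagree),
#' age, woman id, the original combined-reading decision, and the cancer
#' subgroup label (screen-detected vs interval) implied by that decision.
#' The whole table is reproducible from `params$seed`.
#'
#' @param params A [cohort_params()] object.
#' @return A `data.frame` of class `screening_cohort` with columns
#'   `exam_id`, `woman_id`, `age`, `truth`, `ai_score`, `reader1`,
#'   `reader2`, `arbitration`, `subgroup`.
#' @examples
#' cohort <- generate_cohort(cohort_params(n_exams = 500, seed = 42))
#' table(cohort$truth)
#' @export
generate_cohort <- function(params) {
  validate_cohort_params(params)
  n <- params$n_exams
  set.seed(params$seed)
  truth <- as.integer(stats::runif(n) < params$cancer_prevalence)
  age <- draw_ages(n, params$age_mean, params$age_sd, params$age_range)
  woman_id <- draw_woman_ids(n, params$exams_per_woman_mean)
  readers <- draw_reader_decisions(truth, params)
  ai_score <- draw_ai_score(truth, params)
  cohort <- data.frame(exam_id = seq_len(n), woman_id = woman_id,
                       age = age, truth = truth, ai_score = ai_score,
                       reader1 = readers[, "reader1"],
                       reader2 = readers[, "reader2"])
  cohort <- attach_original_arbitrations(cohort, params)
  combined <- ifelse(cohort$reader1 == cohort$reader2,
                     cohort$reader1, cohort$arbitration)
  cohort$subgroup <- classify_subgroup(cohort$truth, combined)
  class(cohort) <- c("screening_cohort", "data.frame")
  cohort
}

#' Validate the structural invariants of a cohort table
#'
#' Checks column presence, value ranges, and the arbitration-presence
#' invariant (an arbitration decision exists if and only if the readers
#' disagree) plus the subgroup/truth consistency rule.
#'
#' @param cohort A cohort data frame.
#' @return The cohort, invisibly; errors describe the first violation found.
#' @export
validate_cohort <- function(cohort) {
  needed <- c("exam_id", "woman_id", "age", "truth", "ai_score",
              "reader1", "reader2", "arbitration", "subgroup")
  missing <- setdiff(needed, names(cohort))
  if (length(missing))
    stop("cohort is missing columns: ", paste(missing, collapse = ", "))
  if (any(!cohort$truth %in% c(0L, 1L))) stop("truth must be 0/1")
  if (any(!cohort$reader1 %in% c(0L, 1L)) ||
      any(!cohort$reader2 %in% c(0L, 1L)))
    stop("reader decisions must be 0/1")
  if (any(cohort$ai_score < 0 | cohort$ai_score > 100))
    stop("ai_score must lie in [0, 100]")
  disagree <- cohort$reader1 != cohort$reader2
  bad <- which(disagree & is.na(cohort$arbitration))
  if (length(bad))
    stop("reader disagreement without arbitration at exam row ", bad[1])
  bad <- which(!disagree & !is.na(cohort$arbitration))
  if (length(bad))
    stop("arbitration present despite reader agreement at exam row ", bad[1])
  bad <- which((cohort$subgroup == "none") != (cohort$truth == 0L))
  if (length(bad))
    stop("subgroup 'none' must coincide with truth = 0 (row ", bad[1], ")")
  invisible(cohort)
}
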