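#' Beta-mixture specification for class-conditional AI scores
#'
#' AI abnormality scores live on a 0--100 percent scale. Each truth class
#' (cancer / non-cancer) gets its own mixture of scaled beta densities:
#' component `k` is `100 * Beta(shape1[k], shape2[k])` with weight
#' `weights[k]`.
#'
#' @param weights Nonnegative component weights; normalised to sum to 1.
#' @param shape1,shape2 Positive beta shape parameters, one per component.
#' @return An object of class `ai_mixture`.
#' @examples
#' ai_mixture(c(0.7, 0.3), shape1 = c(8, 1.2), shape2 = c(1.2, 8))
#' @export
ai_mixture <- function(weights, shape1, shape2) {
  stopifnot(length(weights) == length(shape1),
            length(weights) == length(shape2))
  if (any(weights < 0) || sum(weights) <= 0)
    stop("mixture weights must be nonnegative and not all zero")
  if (any(shape1 <= 0) || any(shape2 <= 0))
    stop("beta shape parameters must be positive")
  structure(list(weights = weights / sum(weights),
                 shape1 = shape1, shape2 = shape2),
            class = "ai_mixture")
}

#' @export
print.ai_mixture <- function(x, ...) {
  cat("AI score mixture on [0,100]:\n")
  for (k in seq_along(x$weights))
    cat(sprintf("  w=%.3f  Beta(%.2f, %.2f)  mean=%.1f\n",
                x$weights[k], x$shape1[k], x$shape2[k],
                100 * x$shape1[k] / (x$shape1[k] + x$shape2[k])))
  invisible(x)
}

#' Mean of a scaled beta mixture
#'
#' @param mix An [ai_mixture()].
#' @return Mean score on the 0--100 scale.
#' @export
mixture_mean <- function(mix) {
  stopifnot(inherits(mix, "ai_mixture"))
  100 * sum(mix$weights * mix$shape1 / (mix$shape1 + mix$shape2))
}

# draw n scores from a scaled beta mixture (uses the current RNG stream)
rmixture <- function(n, mix) {
  k <- sample.int(length(mix$weights), n, replace = TRUE, prob = mix$weights)
  100 * stats::rbeta(n, mix$shape1[k], mix$shape2[k])
}

#' Generative parameters for a synthetic screening cohort
#'
#' Describes the statistical world the generator samples from: exam-level
#' cancer prevalence, the operating points (sensitivity, specificity) of the
#' two screen readers and of the arbitrator, the latent within-exam reader
#' correlation per truth class, class-conditional AI score mixtures, and the
#' age / exams-per-woman structure.
#'
#' Defaults emulate a Danish biennial double-reading programme: prevalence
#' 2033/249402 (about 8.2 cancers per 1000 screens), a second reader more
#' accurate than the first, an arbitrator whose sensitivity closes the
#' combined reading at about 72.6% sensitivity (so roughly 27% of cancers
#' surface as interval cancers), ages truncated-normal on [50, 70] with mean
#' 59.3 and SD 5.9, and about 1.67 exams per woman.
#'
#' Reader dependence is a Gaussian copula per truth class: both readers
#' threshold a shared bivariate normal latent with correlation
#' `reader_dependence_cancer` (resp. `_noncancer`), which preserves the
#' marginal operating points exactly while letting agreement be tuned.
#'
#' @param n_exams Number of screening exams to generate.
#' @param cancer_prevalence Probability an exam is a cancer (truth = 1).
#' @param reader1_sens,reader1_spec First reader operating point.
#' @param reader2_sens,reader2_spec Second reader operating point.
#' @param reader_dependence_cancer,reader_dependence_noncancer Latent
#'   Gaussian-copula correlation between the readers, per truth class,
#'   in `[0, 1)`.
#' @param arbitrator_sens,arbitrator_spec Arbitrator operating point.
#' @param ai_cancer_mixture,ai_noncancer_mixture [ai_mixture()] objects for
#'   the class-conditional AI score distributions.
#' @param age_mean,age_sd Age distribution (years), truncated to `age_range`.
#' @param age_range Screening age window, default `c(50, 70)`.
#' @param exams_per_woman_mean Mean number of exams contributed per woman
#'   (>= 1); exams remain statistically independent, the woman id is
#'   bookkeeping only.
#' @param seed Integer seed making the cohort fully reproducible.
#' @return An object of class `cohort_params` (a validated list).
#' @examples
#' p <- cohort_params(n_exams = 1000, seed = 1)
#' p$cancer_prevalence
#' @export
cohort_params <- function(n_exams = 249402,
                          cancer_prevalence = 2033 / 249402,
                          reader1_sens = 0.60, reader1_spec = 0.965,
                          reader2_sens = 0.72, reader2_spec = 0.970,
                          reader_dependence_cancer = 0.55,
                          reader_dependence_noncancer = 0.55,
                          arbitrator_sens = 0.72, arbitrator_spec = 0.85,
                          ai_cancer_mixture =
                            ai_mixture(c(0.70, 0.30), c(8, 1.2), c(1.2, 8)),
                          ai_noncancer_mixture =
                            ai_mixture(c(0.985, 0.015), c(1.0, 5), c(12, 2)),
                          age_mean = 59.3, age_sd = 5.9,
                          age_range = c(50, 70),
                          exams_per_woman_mean = 249402 / 149495,
                          seed = 20140804L) {
  p <- list(n_exams = as.integer(n_exams),
            cancer_prevalence = cancer_prevalence,
            reader1_sens = reader1_sens, reader1_spec = reader1_spec,
            reader2_sens = reader2_sens, reader2_spec = reader2_spec,
            reader_dependence_cancer = reader_dependence_cancer,
            reader_dependence_noncancer = reader_dependence_noncancer,
            arbitrator_sens = arbitrator_sens,
            arbitrator_spec = arbitrator_spec,
            ai_cancer_mixture = ai_cancer_mixture,
            ai_noncancer_mixture = ai_noncancer_mixture,
            age_mean = age_mean, age_sd = age_sd, age_range = age_range,
            exams_per_woman_mean = exams_per_woman_mean,
            seed = as.integer(seed))
  validate_cohort_params(p)
  structure(p, class = "cohort_params")
}

validate_cohort_params <- function(p) {
  probs <- c(reader1_sens = p$reader1_sens, reader1_spec = p$reader1_spec,
             reader2_sens = p$reader2_sens, reader2_spec = p$reader2_spec,
             arbitrator_sens = p$arbitrator_sens,
             arbitrator_spec = p$arbitrator_spec)
  bad <- probs <= 0 | probs >= 1
  if (any(bad))
    stop("parameters must lie strictly in (0,1): ",
         paste(names(probs)[bad], collapse = ", "))
  # prevalence 0 is admitted as a degenerate cancer-free cohort
  if (p$cancer_prevalence < 0 || p$cancer_prevalence >= 1)
    stop("cancer_prevalence must lie in [0, 1)")
  for (nm in c("reader_dependence_cancer", "reader_dependence_noncancer")) {
    r <- p[[nm]]
    # rho = 1 is the comonotone limit (readers share one latent variable)
    if (!is.finite(r) || r < 0 || r > 1)
      stop(nm, " = ", r, " violates the feasible range [0, 1]")
  }
  if (p$n_exams < 1) stop("n_exams must be >= 1")
  if (p$exams_per_woman_mean < 1) stop("exams_per_woman_mean must be >= 1")
  if (p$age_sd <= 0) stop("age_sd must be positive")
  if (!inherits(p$ai_cancer_mixture, "ai_mixture") ||
      !inherits(p$ai_noncancer_mixture, "ai_mixture"))
    stop("ai_*_mixture must be ai_mixture objects")
  invisible(p)
}

#' @export
print.cohort_params <- function(x, ...) {
  cat(sprintf("Synthetic screening cohort parameters (n = %d, seed = %d)\n",
              x$n_exams, x$seed))
  cat(sprintf("  prevalence %.5f; reader1 (%.3f, %.3f); reader2 (%.3f, %.3f)\n",
              x$cancer_prevalence, x$reader1_sens, x$reader1_spec,
              x$reader2_sens, x$reader2_spec))
  cat(sprintf("  arbitrator (%.3f, %.3f); dependence c=%.2f nc=%.2f\n",
              x$arbitrator_sens, x$arbitrator_spec,
              x$reader_dependence_cancer, x$reader_dependence_noncancer))
  invisible(x)
}
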