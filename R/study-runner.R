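#' Study configuration
#'
#' Bundles everything an end-to-end run needs: the generative cohort
#' parameters, the threshold policy, and the analysis constants.
#'
#' @param cohort A [cohort_params()] object.
#' @param threshold_mode `"match_specificity"` (scenarios 1-2 cutoff matched
#'   at the mean first-reader specificity) or `"fixed"`.
#' @param fixed_threshold Cutoff for scenarios 1-2 when `threshold_mode` is
#'   `"fixed"`.
#' @param moderate_target Triage moderate-band target fraction (default 0.5).
#' @param alpha_coprimary,alpha_secondary,ci_level,mcnemar_exact_cutoff
#'   Analysis constants (defaults 0.00833, 0.05, 0.95, 25).
#' @param split_mode When TRUE, thresholds are selected on one random half
#'   of the cohort and evaluated on the other half, quantifying the optimism
#'   of in-sample selection; default FALSE (select and evaluate on the same
#'   cohort, as screening-programme evaluations usually do).
#' @param seed Master seed; per-stage substreams are derived from it.
#' @return List of class `study_config`.
#' @export
study_config <- function(cohort = cohort_params(),
                         threshold_mode = c("match_specificity", "fixed"),
                         fixed_threshold = NULL,
                         moderate_target = 0.5,
                         alpha_coprimary = 0.05 / 6,
                         alpha_secondary = 0.05,
                         ci_level = 0.95,
                         mcnemar_exact_cutoff = 25,
                         split_mode = FALSE,
                         seed = cohort$seed) {
  threshold_mode <- match.arg(threshold_mode)
  if (threshold_mode == "fixed" && is.null(fixed_threshold))
    stop("threshold_mode 'fixed' requires fixed_threshold")
  stopifnot(alpha_coprimary > 0, alpha_coprimary < 1,
            alpha_secondary > 0, alpha_secondary < 1,
            ci_level > 0, ci_level < 1)
  structure(list(cohort = cohort, threshold_mode = threshold_mode,
                 fixed_threshold = fixed_threshold,
                 moderate_target = moderate_target,
                 alpha_coprimary = alpha_coprimary,
                 alpha_secondary = alpha_secondary,
                 ci_level = ci_level,
                 mcnemar_exact_cutoff = mcnemar_exact_cutoff,
                 split_mode = isTRUE(split_mode),
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Read a study configuration from YAML
#'
#' The `cohort:` block mirrors [cohort_params()] field names; mixtures are
#' given as `weights` / `shape1` / `shape2` lists. Top-level keys mirror
#' [study_config()] arguments.
#'
#' @param path Path to a YAML file.
#' @return A `study_config` object.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  ck <- y$cohort %||% list()
  for (nm in c("ai_cancer_mixture", "ai_noncancer_mixture"))
    if (!is.null(ck[[nm]]))
      ck[[nm]] <- ai_mixture(unlist(ck[[nm]]$weights),
                             unlist(ck[[nm]]$shape1),
                             unlist(ck[[nm]]$shape2))
  cohort <- do.call(cohort_params, ck)
  top <- y[setdiff(names(y), "cohort")]
  do.call(study_config, c(list(cohort = cohort), top))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply labeled exclusion rules with flowchart accounting
#'
#' Each rule is a predicate returning TRUE for rows to EXCLUDE. A row
#' failing several rules is attributed to the first failing rule in the
#' declared order, and removed once.
#'
#' @param raw_cohort A data frame.
#' @param rules Named list of predicate functions `function(cohort)` ->
#'   logical vector.
#' @return List with `cohort` (the retained rows) and `accounting`
#'   (a [flow_accounting()] object).
#' @export
apply_exclusions <- function(raw_cohort, rules = list()) {
  n0 <- nrow(raw_cohort)
  assigned <- rep(NA_character_, n0)
  for (nm in names(rules)) {
    hit <- rules[[nm]](raw_cohort)
    assigned[is.na(assigned) & hit] <- nm
  }
  counts <- vapply(names(rules), function(nm) sum(assigned == nm, na.rm = TRUE),
                   integer(1))
  list(cohort = raw_cohort[is.na(assigned), , drop = FALSE],
       accounting = flow_accounting(n0, counts))
}

#' Flowchart accounting record
#'
#' @param initial_n Starting sample size.
#' @param exclusions Named integer vector of per-reason exclusion counts.
#' @return List of class `flow_accounting` with `initial_n`, `exclusions`,
#'   `total_excluded`, `exclusion_rate_pct`, `final_n`; the balance
#'   `final_n = initial_n - sum(exclusions)` holds by construction.
#' @examples
#' fa <- flow_accounting(272008, c(technical_recall = 9, no_db_match = 4734,
#'   no_followup = 1960, irretrievable = 1969, unsupported_type = 13923,
#'   ai_rejected = 11))
#' fa$final_n  # 249402
#' @export
flow_accounting <- function(initial_n, exclusions = integer()) {
  total <- sum(exclusions)
  if (total > initial_n) stop("exclusions exceed the initial sample")
  structure(list(initial_n = as.integer(initial_n),
                 exclusions = exclusions,
                 total_excluded = as.integer(total),
                 exclusion_rate_pct = 100 * total / initial_n,
                 final_n = as.integer(initial_n - total)),
            class = "flow_accounting")
}

#' @export
print.flow_accounting <- function(x, ...) {
  cat(sprintf("Flow: %d screened", x$initial_n))
  if (length(x$exclusions))
    cat(" - [", paste(sprintf("%s %d", names(x$exclusions), x$exclusions),
                      collapse = ", "), "]")
  cat(sprintf(" = %d (%.2f%% excluded)\n", x$final_n, x$exclusion_rate_pct))
  invisible(x)
}

#' Write / read a cohort CSV
#'
#' One row per exam; the `arbitration` field is empty (not 0) when absent.
#' `read_cohort()` validates the arbitration-presence invariant and reports
#' the offending row on violation.
#'
#' @param cohort A cohort data frame.
#' @param path File path.
#' @return `read_cohort()` returns the validated cohort; `write_cohort()`
#'   the path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, na.strings = "", fileEncoding = "UTF-8",
                            colClasses = c(exam_id = "integer",
                                           woman_id = "integer",
                                           age = "numeric", truth = "integer",
                                           ai_score = "numeric",
                                           reader1 = "integer",
                                           reader2 = "integer",
                                           arbitration = "integer",
                                           subgroup = "character"))
  validate_cohort(cohort)
  class(cohort) <- c("screening_cohort", "data.frame")
  cohort
}

#' Run the full study end to end
#'
#' Generates (or accepts) a cohort, selects thresholds, runs the combined
#' reading and all three AI-integrated scenarios, and computes per-scenario
#' accuracy summaries, paired comparisons, subgroup sensitivities, and
#' workload tallies. Deterministic given the configuration.
#'
#' @param config A [study_config()].
#' @param cohort Optional pre-built cohort (e.g. from [read_cohort()]);
#'   when NULL one is generated from `config$cohort`.
#' @param output_dir Optional directory; when given, writes the cohort CSV,
#'   thresholds JSON, per-scenario outcome CSVs, report tables (TSV), the
#'   comparisons JSON, and a run log.
#' @return List of class `study_result`: `cohort`, `thresholds`, `profile`,
#'   `outcomes` (named list of `scenario_outcome`s), `summaries`,
#'   `comparisons`, `subgroups`, `workload`, `config`.
#' @export
run_study <- function(config = study_config(), cohort = NULL,
                      output_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  if (is.null(cohort)) cohort <- generate_cohort(config$cohort)
  validate_cohort(cohort)

  eval_cohort <- cohort
  select_cohort <- cohort
  if (config$split_mode) {
    set.seed(scenario_seed(config$seed, "split"))
    half <- sample.int(nrow(cohort)) <= nrow(cohort) / 2
    select_cohort <- cohort[half, , drop = FALSE]
    eval_cohort <- cohort[!half, , drop = FALSE]
  }
  combined_sel <- combined_reading(select_cohort)
  combined <- combined_reading(eval_cohort)
  profile <- estimate_arbitrator_profile(select_cohort)

  # scenarios 1-2 share one cutoff: matched at mean first-reader specificity
  if (config$threshold_mode == "match_specificity") {
    r1 <- select_cohort[select_cohort$truth == 0L, "reader1"]
    ts <- threshold_at_specificity(
      select_cohort$ai_score[select_cohort$truth == 0L], 1 - mean(r1))
  } else {
    ts <- list(threshold = config$fixed_threshold,
               realized_specificity = NA_real_)
  }
  triage <- select_triage_thresholds(select_cohort, combined_sel,
                                     moderate_target = config$moderate_target)

  ai_recall <- dichotomize_ai(eval_cohort$ai_score, ts$threshold)
  outcomes <- list(
    combined = combined,
    ai_first = scenario_reader_replacement(
      eval_cohort, ai_recall, "first", profile,
      seed = scenario_seed(config$seed, "ai_first")),
    ai_second = scenario_reader_replacement(
      eval_cohort, ai_recall, "second", profile,
      seed = scenario_seed(config$seed, "ai_second")),
    ai_triage = scenario_triage(eval_cohort, triage$triage_low,
                                triage$triage_high, combined))

  summaries <- lapply(outcomes, function(o)
    accuracy_summary(confusion_counts(o$final_recall, eval_cohort$truth),
                     o$arbitration_used, config$ci_level))
  scen <- c("ai_first", "ai_second", "ai_triage")
  comparisons <- lapply(stats::setNames(scen, scen), function(sc)
    compare_scenarios(eval_cohort, outcomes[[sc]], combined,
                      config$alpha_coprimary, config$alpha_secondary,
                      config$mcnemar_exact_cutoff))
  workload <- lapply(stats::setNames(scen, scen), function(sc)
    tally_workload(outcomes[[sc]], combined))
  subgroups <- lapply(outcomes, function(o) list(
    screen_detected = subgroup_sensitivity(o, eval_cohort, "screen_detected",
                                           config$ci_level),
    interval = subgroup_sensitivity(o, eval_cohort, "interval",
                                    config$ci_level)))

  result <- structure(list(cohort = eval_cohort,
                           thresholds = list(scenario_threshold = ts$threshold,
                                             realized_specificity =
                                               ts$realized_specificity,
                                             triage = triage),
                           profile = profile, outcomes = outcomes,
                           summaries = summaries, comparisons = comparisons,
                           subgroups = subgroups, workload = workload,
                           config = config),
                      class = "study_result")
  if (!is.null(output_dir)) write_study_outputs(result, output_dir)
  result
}

# serialize the report bundle; plain-text formats only
write_study_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(result$cohort, file.path(dir, "cohort.csv"))
  tri <- result$thresholds$triage
  jsonlite::write_json(
    list(scenario_threshold = result$thresholds$scenario_threshold,
         realized_specificity = result$thresholds$realized_specificity,
         triage_low = tri$triage_low, triage_high = tri$triage_high,
         realized_moderate_fraction = tri$realized_moderate_fraction,
         realized_recall_rate = tri$realized_recall_rate,
         arbitrator = result$profile[c("sens", "spec")]),
    file.path(dir, "thresholds.json"), auto_unbox = TRUE, digits = NA)
  for (nm in names(result$outcomes))
    utils::write.csv(result$outcomes[[nm]],
                     file.path(dir, paste0("outcomes_", nm, ".csv")),
                     row.names = FALSE)
  utils::write.table(summary_table(result), file.path(dir, "table1_accuracy.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(workload_table(result), file.path(dir, "table2_workload.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(subgroup_table(result), file.path(dir, "table3_subgroups.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(lapply(result$comparisons, function(d)
    as.list(as.data.frame(d))), file.path(dir, "comparisons.json"),
    auto_unbox = TRUE, digits = NA, na = "null")
  writeLines(c(sprintf("mammoscreen %s", utils::packageVersion("mammoscreen")),
               sprintf("R %s", getRversion()),
               sprintf("seed %d", result$config$seed),
               sprintf("rng substreams: ai_first=%d ai_second=%d ai_triage=%d",
                       scenario_seed(result$config$seed, "ai_first"),
                       scenario_seed(result$config$seed, "ai_second"),
                       scenario_seed(result$config$seed, "ai_triage")),
               sprintf("n_exams %d", nrow(result$cohort))),
             file.path(dir, "run_log.txt"))
  invisible(dir)
}

# Table-1-shaped per-scenario accuracy summary
summary_table <- function(result) {
  rows <- lapply(names(result$summaries), function(nm) {
    s <- result$summaries[[nm]]
    g <- function(m) if (m$defined) 100 * m$estimate else NA_real_
    data.frame(scenario = nm,
               sensitivity_pct = g(s$sensitivity),
               specificity_pct = g(s$specificity),
               ppv_pct = g(s$ppv), npv_pct = g(s$npv),
               recall_rate_pct = g(s$recall_rate),
               arbitration_rate_pct = g(s$arbitration_rate),
               cdr_per_1000 = s$cdr_per_1000, auc = s$auc)
  })
  do.call(rbind, rows)
}

# Table-2-shaped cross-tabulation + workload
workload_table <- function(result) {
  rows <- lapply(names(result$outcomes), function(nm) {
    cc <- result$summaries[[nm]]$counts
    w <- if (nm == "combined")
      list(total_reads_scenario = sum(result$outcomes$combined$human_reads),
           relative_reduction = 0)
    else result$workload[[nm]]
    data.frame(scenario = nm, tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn,
               total_reads = w$total_reads_scenario,
               read_reduction_pct = w$relative_reduction)
  })
  do.call(rbind, rows)
}

# Table-3-shaped subgroup sensitivities
subgroup_table <- function(result) {
  rows <- lapply(names(result$subgroups), function(nm) {
    sg <- result$subgroups[[nm]]
    g <- function(m) if (m$defined) 100 * m$estimate else NA_real_
    data.frame(scenario = nm,
               screen_detected_sens_pct = g(sg$screen_detected),
               interval_sens_pct = g(sg$interval))
  })
  do.call(rbind, rows)
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("AI-integrated screening study on %d exams (seed %d)\n",
              nrow(x$cohort), x$config$seed))
  cat(sprintf("  scenario 1-2 threshold %.3f (realized spec %.4f)\n",
              x$thresholds$scenario_threshold,
              x$thresholds$realized_specificity))
  print(x$thresholds$triage)
  for (nm in names(x$workload))
    cat(sprintf("  %s: read reduction %.1f%%\n", nm,
                x$workload[[nm]]$relative_reduction))
  invisible(x)
}
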