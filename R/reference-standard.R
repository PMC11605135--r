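#' Classify cancers as screen-detected or interval
#'
#' The reference standard fixes each exam's truth label (cancer within the
#' follow-up window) and splits cancers by whether the ORIGINAL combined
#' double reading recalled them: recalled cancers are screen-detected,
#' non-recalled cancers are interval cancers. Non-cancers get `"none"`.
#' The label is a property of the original reading, so it is identical
#' across all AI-integrated scenarios.
#'
#' @param truth Integer 0/1 truth labels.
#' @param combined_recall Integer 0/1 original combined-reading decisions.
#' @return Character vector: `"screen_detected"`, `"interval"`, or `"none"`.
#' @export
classify_subgroup <- function(truth, combined_recall) {
  stopifnot(length(truth) == length(combined_recall))
  ifelse(truth == 0L, "none",
         ifelse(combined_recall == 1L, "screen_detected", "interval"))
}

#' Cancer subgroup composition
#'
#' Fractions of screen-detected and interval cancers among all cancers,
#' reported as percentages.
#'
#' @param cohort A cohort data frame with `truth` and `subgroup` columns.
#' @return List with counts, `pct_screen_detected`, `pct_interval`, and a
#'   `defined` flag (FALSE, with NA percentages, when the cohort holds no
#'   cancers).
#' @examples
#' coh <- data.frame(truth = c(1, 1, 1, 1, 0),
#'                   subgroup = c("screen_detected", "screen_detected",
#'                                "screen_detected", "interval", "none"))
#' subgroup_composition(coh)$pct_screen_detected  # 75
#' @export
subgroup_composition <- function(cohort) {
  cancers <- cohort[cohort$truth == 1L, , drop = FALSE]
  n <- nrow(cancers)
  if (n == 0L)
    return(list(n_cancers = 0L, n_screen_detected = 0L, n_interval = 0L,
                pct_screen_detected = NA_real_, pct_interval = NA_real_,
                defined = FALSE))
  n_sd <- sum(cancers$subgroup == "screen_detected")
  n_iv <- sum(cancers$subgroup == "interval")
  list(n_cancers = n, n_screen_detected = n_sd, n_interval = n_iv,
       pct_screen_detected = 100 * n_sd / n,
       pct_interval = 100 * n_iv / n,
       defined = TRUE)
}
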