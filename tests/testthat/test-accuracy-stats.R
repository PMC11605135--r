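test_that("confusion counts match hand tallies", {
  cc <- confusion_counts(c(1L, 0L), c(1L, 0L))
  expect_equal(cc[c("tp", "tn", "fp", "fn")], list(tp = 1L, tn = 1L, fp = 0L, fn = 0L))
  all_pos <- confusion_counts(rep(1L, 7), rep(1L, 7))
  expect_equal(all_pos$tp, 7L)
  # 8-row hand fixture
  rec <- c(1, 1, 0, 0, 1, 0, 1, 0)
  tru <- c(1, 0, 1, 0, 1, 0, 0, 1)
  cc <- confusion_counts(rec, tru)
  expect_equal(unlist(cc), c(tp = 2, fp = 2, fn = 2, tn = 2, n = 8))
  expect_error(confusion_counts(1:3, 1:2), "equal length")
})

test_that("accuracy summary arithmetic and degenerate denominators", {
  cc <- confusion_counts(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
                         c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0))
  s <- accuracy_summary(cc, arbitration_flags = c(TRUE, rep(FALSE, 9)))
  expect_equal(s$sensitivity$estimate, 0.75)
  expect_equal(s$ppv$estimate, 0.75)
  expect_equal(s$npv$estimate, 5 / 6)
  expect_equal(s$recall_rate$estimate, 0.4)
  expect_equal(s$arbitration_rate$estimate, 0.1)
  expect_equal(s$cdr_per_1000, 300)
  # cdr definitional: tp=6 in 1000
  cc2 <- confusion_counts(c(rep(1, 6), rep(0, 994)), c(rep(1, 6), rep(0, 994)))
  expect_equal(accuracy_summary(cc2, rep(FALSE, 1000))$cdr_per_1000, 6)
  # perfect classifier
  expect_equal(accuracy_summary(cc2, rep(FALSE, 1000))$sensitivity$estimate, 1)
  expect_equal(accuracy_summary(cc2, rep(FALSE, 1000))$recall_rate$estimate,
               6 / 1000)
  # zero-denominator metrics are flagged, not zeroed
  cc3 <- confusion_counts(rep(0, 5), rep(0, 5))
  s3 <- accuracy_summary(cc3, rep(FALSE, 5))
  expect_false(s3$ppv$defined)
  expect_true(is.na(s3$ppv$estimate))
})

test_that("Clopper-Pearson matches the closed forms and contains k/n", {
  # k = 0: upper bound solves (1 - u)^n = alpha/2
  ci <- clopper_pearson(0, 10, 0.95)
  expect_equal(ci[["lower"]], 0)
  expect_equal(ci[["upper"]], 1 - (0.025)^(1 / 10), tolerance = 1e-10)
  # k = n by complement symmetry
  ci <- clopper_pearson(10, 10, 0.95)
  expect_equal(ci[["upper"]], 1)
  expect_equal(ci[["lower"]], (0.025)^(1 / 10), tolerance = 1e-10)
  # containment + agreement with the binom.test oracle, width shrinks with n
  for (k in c(1, 5, 9)) for (n in c(10, 50)) {
    ci <- clopper_pearson(k * n / 10, n, 0.95)
    expect_true(ci[["lower"]] <= k / 10 && k / 10 <= ci[["upper"]])
    oracle <- binom.test(k * n / 10, n)$conf.int
    expect_equal(unname(ci), as.numeric(oracle), tolerance = 1e-8)
  }
  w <- function(n) diff(clopper_pearson(round(n / 2), n))
  expect_true(w(200) < w(50) && w(50) < w(10))
  expect_error(clopper_pearson(5, 4), "successes")
})

test_that("McNemar branches, symmetry, and exact enumeration", {
  expect_equal(mcnemar_test(0, 0)$p_value, 1)
  expect_equal(mcnemar_test(5, 5)$p_value, 1)
  # asymptotic arithmetic (cutoff lowered so the example takes that branch)
  m <- mcnemar_test(15, 5, exact_cutoff = 10)
  expect_equal(m$statistic, 5)
  expect_equal(m$p_value, pchisq(5, 1, lower.tail = FALSE))
  # exact branch: b = 2, c = 0 -> 2 * (1/2)^2
  expect_equal(mcnemar_test(2, 0)$p_value, 0.5)
  expect_equal(mcnemar_test(2, 0)$method, "exact")
  # exact enumeration oracle for a few small tables
  for (bc in list(c(3, 1), c(7, 2), c(0, 4))) {
    p <- mcnemar_test(bc[1], bc[2])$p_value
    oracle <- min(1, 2 * pbinom(min(bc), sum(bc), 0.5))
    expect_equal(p, oracle)
  }
  # symmetry under (b, c) swap
  for (bc in list(c(3, 1), c(30, 18))) {
    a <- mcnemar_test(bc[1], bc[2]); b <- mcnemar_test(bc[2], bc[1])
    expect_equal(a$p_value, b$p_value)
    expect_equal(a$statistic, b$statistic)
  }
})

test_that("paired predictive-value score test: null and degenerate contracts", {
  set.seed(9)
  truth <- rbinom(60, 1, 0.3)
  rec <- rbinom(60, 1, 0.4)
  same <- paired_pv_score_test(truth, rec, rec, "ppv")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # disjoint positives with equal empirical PPVs
  truth <- c(1, 0, 1, 0)
  a <- c(1, 1, 0, 0)
  b <- c(0, 0, 1, 1)
  z <- paired_pv_score_test(truth, a, b, "ppv")
  expect_equal(z$statistic, 0)
  expect_equal(z$p_value, 1)
  expect_error(paired_pv_score_test(c(1, 0), c(0, 0), c(1, 0), "ppv"),
               "arm a")
})

test_that("score test tracks the within-subject permutation oracle", {
  # a strong-effect, a reverse-direction, and an exact-null fixture
  for (cf in pv_fixture_configs[c(1, 4, 7)]) {
    f <- do.call(build_pv_fixture, as.list(cf))
    p_asy <- paired_pv_score_test(f$truth, f$a, f$b, "ppv")$p_value
    p_perm <- pv_permutation_p(f$truth, f$a, f$b, "ppv", reps = 4000,
                               seed = 7)
    expect_lt(abs(p_asy - p_perm), 0.02)
  }
})

test_that("AUC operations agree with their oracles", {
  expect_equal(operating_point_auc(1, 1), 1)
  expect_equal(operating_point_auc(1, 0), 0.5)
  expect_equal(operating_point_auc(0.8, 0.9), 0.85)
  expect_error(operating_point_auc(1.2, 0.5), "0, 1")

  expect_equal(empirical_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  expect_equal(empirical_auc(rep(4, 6), c(1, 0, 1, 0, 0, 1)), 0.5)
  scores <- c(3, 7, 7, 1, 9, 5)
  truth <- c(0, 1, 0, 0, 1, 1)
  expect_equal(empirical_auc(scores, truth), auc_bruteforce(scores, truth))
  expect_error(empirical_auc(1:4, rep(1, 4)), "both classes")
  # binary score reduces to the one-point trapezoid
  set.seed(3)
  truth <- rbinom(300, 1, 0.3)
  dec <- rbinom(300, 1, ifelse(truth == 1, 0.8, 0.2))
  cc <- confusion_counts(dec, truth)
  expect_equal(empirical_auc(dec, truth),
               operating_point_auc(cc$tp / (cc$tp + cc$fn),
                                   cc$tn / (cc$tn + cc$fp)))
})

test_that("Welch t test behaves as specified", {
  x <- c(1, 2, 3, 4)
  same <- welch_t_test(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  set.seed(4)
  a <- rnorm(1000, 0); b <- rnorm(1000, 1)
  expect_lt(welch_t_test(a, b)$p_value, 0.001)
  fwd <- welch_t_test(a, b); rev <- welch_t_test(b, a)
  expect_equal(fwd$statistic, -rev$statistic)
  expect_equal(fwd$p_value, rev$p_value)
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
})

test_that("compare_scenarios deltas, sign convention, and alphas", {
  coh <- generate_cohort(small_params(n = 4000, seed = 19))
  combined <- combined_reading(coh)
  # identical scenario: all deltas 0, all p = 1
  cmp <- compare_scenarios(coh, combined, combined)
  expect_true(all(cmp$delta_pp == 0))
  expect_true(all(cmp$p_value == 1))
  expect_equal(cmp$alpha[cmp$endpoint == "sensitivity"], 0.05 / 6)
  expect_equal(cmp$alpha[cmp$endpoint == "recall_rate"], 0.05)

  # scenario recalling one extra cancer: positive sensitivity delta
  extra <- combined
  flip <- which(coh$truth == 1L & combined$final_recall == 0L)[1]
  extra$final_recall[flip] <- 1L
  cmp <- compare_scenarios(coh, extra, combined)
  expect_gt(cmp$delta_pp[cmp$endpoint == "sensitivity"], 0)
  expect_equal(cmp$delta_pp[cmp$endpoint == "sensitivity"],
               100 / sum(coh$truth == 1L))
})
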