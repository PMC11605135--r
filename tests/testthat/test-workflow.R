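test_that("AI dichotomization is strict at the threshold", {
  expect_equal(dichotomize_ai(81.0, 80.99), 1L)
  expect_equal(dichotomize_ai(80.99, 80.99), 0L)
  expect_equal(dichotomize_ai(0, 0), 0L)
  expect_equal(dichotomize_ai(c(10, 20, 30), 20), c(0L, 0L, 1L))
  expect_error(dichotomize_ai(101, 50), "0, 100")
  expect_error(dichotomize_ai(50, -1), "0, 100")
})

test_that("combined reading follows agreement/arbitration rules", {
  coh <- make_cohort(truth = c(1, 1, 0), reader1 = c(1, 1, 0),
                     reader2 = c(1, 0, 0), arbitration = c(NA, 0, NA))
  out <- combined_reading(coh)
  expect_equal(out$final_recall, c(1L, 0L, 0L))
  expect_equal(out$human_reads, c(2L, 3L, 2L))
  expect_equal(out$arbitration_source, c("none", "original", "none"))
  # a disagreement with a missing arbitration violates the data contract
  bad <- make_cohort(truth = 1, reader1 = 1, reader2 = 0, arbitration = NA)
  expect_error(combined_reading(bad), "arbitration")
})

test_that("arbitrator profile estimation and its edge contracts", {
  coh <- make_cohort(truth = c(1, 1, 0, 0), reader1 = c(1, 1, 1, 0),
                     reader2 = c(0, 0, 0, 1), arbitration = c(1, 1, 0, 0))
  prof <- estimate_arbitrator_profile(coh)
  expect_equal(prof$sens, 1)
  expect_equal(prof$spec, 1)
  expect_equal(prof$n_cancer_est, 2L)
  no_cancer_arb <- make_cohort(truth = c(1, 0), reader1 = c(1, 1),
                               reader2 = c(1, 0), arbitration = c(NA, 1))
  expect_error(estimate_arbitrator_profile(no_cancer_arb), "cancers")
})

test_that("simulated arbitration hits the profile operating point", {
  expect_equal(simulate_arbitration(rep(1L, 5), arbitrator_profile(1, 0.5)),
               rep(1L, 5))
  expect_equal(simulate_arbitration(rep(0L, 5), arbitrator_profile(0.5, 1)),
               rep(0L, 5))
  set.seed(2)
  draws <- simulate_arbitration(rep(1L, 100000), arbitrator_profile(0.7, 0.8))
  expect_lt(abs(mean(draws) - 0.7), 3 * sqrt(0.7 * 0.3 / 100000))
})

test_that("reader-replacement rules hold for all 24 enumerable cases", {
  profile <- arbitrator_profile(1, 0.5)  # truth = 1 cases: simulation recalls
  for (replaced in c("first", "second"))
    for (r1 in 0:1) for (r2 in 0:1) for (ai in 0:1) {
      arbs <- if (r1 != r2) 0:1 else NA_integer_
      for (arb in arbs) {
        coh <- make_cohort(truth = 1, reader1 = r1, reader2 = r2,
                           arbitration = arb)
        out <- scenario_reader_replacement(coh, ai, replaced, profile,
                                           seed = 1)
        retained <- if (replaced == "first") r2 else r1
        if (ai == retained) {
          expect_equal(out$final_recall, retained)
          expect_equal(out$human_reads, 1L)
          expect_false(out$arbitration_used)
          expect_equal(out$arbitration_source, "none")
        } else {
          expect_equal(out$human_reads, 2L)
          expect_true(out$arbitration_used)
          if (!is.na(arb)) {
            expect_equal(out$final_recall, arb)
            expect_equal(out$arbitration_source, "original")
          } else {
            expect_equal(out$final_recall, 1L)  # sens-1 profile, truth 1
            expect_equal(out$arbitration_source, "simulated")
          }
        }
      }
    }
})

test_that("AI replicating the replaced reader reproduces combined reading", {
  coh <- generate_cohort(small_params(n = 6000, seed = 17))
  combined <- combined_reading(coh)
  profile <- estimate_arbitrator_profile(coh)
  for (replaced in c("first", "second")) {
    ai <- if (replaced == "first") coh$reader1 else coh$reader2
    out <- scenario_reader_replacement(coh, ai, replaced, profile, seed = 1)
    expect_identical(out$final_recall, combined$final_recall)
  }
})

test_that("triage bands tile the score axis and route correctly", {
  coh <- make_cohort(truth = c(0, 0, 1), reader1 = c(1, 0, 1),
                     reader2 = c(0, 0, 1), arbitration = c(1, NA, NA),
                     ai_score = c(96.0, 2.0, 50.0))
  combined <- combined_reading(coh)
  out <- scenario_triage(coh, 3.36, 95.29, combined)
  expect_equal(out$final_recall, c(1L, 0L, 1L))
  expect_equal(out$human_reads, c(0L, 0L, 2L))
  expect_equal(out$arbitration_source, c("none", "none", "none"))
  # moderate case inherits combined's arbitration provenance
  expect_true(scenario_triage(coh, 3.36, 97, combined)$arbitration_used[1])
  expect_error(scenario_triage(coh, 50, 50, combined), "low < high")

  score <- runif(500, 0, 100)
  band <- triage_band(score, 20, 80)
  expect_true(all((score < 20) == (band == "low")))
  expect_true(all((score >= 80) == (band == "high")))
  expect_true(all((score >= 20 & score < 80) == (band == "moderate")))
})

test_that("workload accounting matches enumeration and algebra", {
  # zero arbitrations anywhere: exactly 50% reduction for reader replacement
  coh <- make_cohort(truth = rep(0, 4), reader1 = rep(0, 4),
                     reader2 = rep(0, 4))
  combined <- combined_reading(coh)
  s1 <- scenario_reader_replacement(coh, rep(0L, 4), "first",
                                    arbitrator_profile(1, 1), seed = 1)
  expect_equal(tally_workload(s1, combined)$relative_reduction, 50)

  # 10-exam mixed fixture vs an independent hand count
  coh <- make_cohort(truth = c(1, 1, 0, 0, 0, 1, 0, 0, 1, 0),
                     reader1 = c(1, 1, 0, 1, 0, 0, 0, 1, 1, 0),
                     reader2 = c(1, 0, 0, 0, 0, 1, 0, 1, 0, 0),
                     arbitration = c(NA, 1, NA, 0, NA, 1, NA, NA, 0, NA))
  combined <- combined_reading(coh)
  ai <- c(1L, 0L, 0L, 0L, 1L, 1L, 0L, 1L, 0L, 0L)
  out <- scenario_reader_replacement(coh, ai, "first",
                                     arbitrator_profile(1, 1), seed = 4)
  # combined reads: 2 per exam + 1 per original disagreement (4) = 24
  expect_equal(sum(combined$human_reads), 24L)
  # scenario reads: 1 per exam + 1 per AI/reader-2 disagreement
  hand_disagree <- sum(ai != coh$reader2)
  expect_equal(sum(out$human_reads), 10L + hand_disagree)
  w <- tally_workload(out, combined)
  expect_equal(w$relative_reduction, 100 * (1 - (10 + hand_disagree) / 24))

  # algebraic identity: reduction = 100 * (1 - (1 + s) / (2 + r))
  r <- mean(combined$arbitration_used)
  s <- mean(out$arbitration_used)
  expect_equal(w$relative_reduction, 100 * (1 - (1 + s) / (2 + r)))

  expect_error(tally_workload(out[1:5, ], combined), "same exam set")
})

test_that("scenario outcomes are reproducible from their substream seed", {
  coh <- generate_cohort(small_params(n = 3000, seed = 8))
  ai <- dichotomize_ai(coh$ai_score, 30)
  prof <- arbitrator_profile(0.7, 0.85)
  a <- scenario_reader_replacement(coh, ai, "second", prof, seed = 123)
  b <- scenario_reader_replacement(coh, ai, "second", prof, seed = 123)
  expect_identical(a, b)
})
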