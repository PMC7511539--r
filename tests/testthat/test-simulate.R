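perfect_params <- function() {
  learner_params(p0 = 1, asymptote = 1, insertion_rate = 0,
                 timing_cv0 = 0, timing_cv_floor = 0)
}

test_that("the noiseless limit reproduces the target exactly", {
  withr::local_seed(1)
  m <- study_melody(1)
  p <- simulate_trial(perfect_params(), 1, m)
  s <- score_trial(p, m)
  expect_equal(s$pitch_accuracy, 100)
  expect_equal(s$rhythm_accuracy, 100)
  expect_equal(p$events$onset, melody_onsets(m))
})

test_that("a non-learner's pitch accuracy collapses", {
  withr::local_seed(2)
  m <- study_melody(1)
  accs <- replicate(200, {
    p <- simulate_trial(learner_params(p0 = 0, asymptote = 0,
                                       insertion_rate = 0), 1, m)
    score_trial(p, m)$pitch_accuracy
  })
  # substitutions over 4 alternatives leave only chance-level matches
  expect_lt(mean(accs), 45)
})

test_that("simulated rhythm accuracy matches the lognormal closed form", {
  withr::local_seed(3)
  m <- study_melody(1)
  cv <- 0.05
  params <- learner_params(p0 = 1, asymptote = 1, insertion_rate = 0,
                           timing_cv0 = cv, timing_cv_floor = cv)
  accs <- replicate(1000, {
    p <- simulate_trial(params, 1, m)
    score_trial(p, m)$rhythm_accuracy
  })
  s2 <- log(1 + cv^2)
  q <- plnorm(1.1, -s2 / 2, sqrt(s2)) - plnorm(0.9, -s2 / 2, sqrt(s2))
  expect_lt(abs(mean(accs) - 100 * q), 3)
})

test_that("the criterion stop rule looks at the last three test trials", {
  expect_true(criterion_check(c(TRUE, TRUE, TRUE)))
  expect_false(criterion_check(c(TRUE, FALSE, TRUE, TRUE)))
  expect_false(criterion_check(c(TRUE, TRUE)))
  expect_true(criterion_check(c(FALSE, TRUE, TRUE, TRUE)))
})

test_that("acquisition stops at the criterion or runs all six blocks", {
  withr::local_seed(4)
  m <- study_melody(1)
  # perfect learner: the qualifying run inside blocks 1-3 stops practice
  # once the minimum three blocks are complete
  acq <- simulate_acquisition(perfect_params(), m)
  expect_true(acq$stopped_early)
  expect_identical(acq$t_final, 15L)
  expect_true(all(acq$scores$correct))
  # non-learner: all six blocks, 30 test trials
  acq2 <- simulate_acquisition(learner_params(p0 = 0.1, asymptote = 0.1), m)
  expect_false(acq2$stopped_early)
  expect_identical(acq2$t_final, 30L)
  expect_identical(unique(acq2$scores$block), as.numeric(1:6))
  # without the criterion (transfer) even a perfect learner plays them all
  acq3 <- simulate_acquisition(perfect_params(), m, apply_criterion = FALSE)
  expect_identical(acq3$t_final, 30L)
})

test_that("rhythm-only errors with perfect pitches still stop practice", {
  withr::local_seed(5)
  m <- study_melody(1)
  noisy_timing <- learner_params(p0 = 1, asymptote = 1, insertion_rate = 0,
                                 timing_cv0 = 0.3, timing_cv_floor = 0.3)
  acq <- simulate_acquisition(noisy_timing, m)
  expect_true(acq$stopped_early)
  expect_identical(acq$t_final, 15L)
  expect_lt(mean(acq$scores$rhythm_accuracy), 100)
})

test_that("last-10 averaging follows the windowing rule", {
  expect_equal(last10_average(rep(80, 20)), 80)
  expect_equal(last10_average(c(rep(0, 10), 91:100)), 95.5)
  # 13 trials at criterion: mean of trials 4-13
  x <- c(10, 20, 30, 41:50)
  expect_equal(last10_average(x), mean(41:50))
  expect_message(v <- last10_average(c(70, 80)), "fewer than 10")
  expect_equal(v, 75)
  expect_error(last10_average(numeric(0)), "no trials")
})

test_that("a fixed config yields a byte-identical trial table", {
  cfg <- cohort_config(n_hiit = 3, n_liit = 3, seed = 99)
  t1 <- simulate_study(cfg)
  t2 <- simulate_study(cfg)
  attr(t1, "config") <- NULL
  attr(t2, "config") <- NULL
  expect_identical(t1, t2)
  # and the seed matters
  t3 <- simulate_study(cohort_config(n_hiit = 3, n_liit = 3, seed = 100))
  attr(t3, "config") <- NULL
  expect_false(identical(t1, t3))
})

test_that("simulate_study covers the session plan with valid scores", {
  tr <- simulate_study(cohort_config(n_hiit = 3, n_liit = 2, seed = 11))
  expect_setequal(unique(tr$session), c("Acq", "R1", "R24", "R7", "Tran"))
  expect_identical(length(unique(tr$participant_id)), 5L)
  expect_true(all(tr$pitch_accuracy >= 0 & tr$pitch_accuracy <= 100))
  expect_true(all(tr$rhythm_accuracy >= 0 & tr$rhythm_accuracy <= 100))
  # 10 test trials per retention session per participant
  ret <- tr[tr$session == "R24", ]
  expect_true(all(table(ret$participant_id) == 10))
  # transfer always has 6 blocks x 5 trials
  tran <- tr[tr$phase == "transfer", ]
  expect_true(all(table(tran$participant_id) == 30))
  # group sizes as configured
  expect_identical(length(unique(tr$participant_id[tr$group == "HIIT"])), 3L)
  # musical training constant within participant, non-negative
  mt <- tapply(tr$musical_training, tr$participant_id,
               function(z) length(unique(z)))
  expect_true(all(mt == 1))
})

test_that("ensemble mean accuracy is non-decreasing when learning rate > 0", {
  withr::local_seed(12)
  m <- study_melody(1)
  params <- learner_params(p0 = 0.3, asymptote = 0.9, rate = 0.15,
                           insertion_rate = 0)
  trials <- c(1, 5, 10, 20, 40)
  means <- vapply(trials, function(t)
    mean(replicate(150, {
      ev <- simulate_trial(params, t, m)
      score_trial(ev, m)$pitch_accuracy
    })), 0)
  expect_true(all(diff(means) > -2)) # monotone up to Monte-Carlo wiggle
  expect_gt(means[5], means[1])
})

test_that("group effects shift scores additively with truncation", {
  cfg0 <- cohort_config(n_hiit = 3, n_liit = 3, seed = 21,
                        consolidation_gain = 0)
  cfg10 <- cohort_config(n_hiit = 3, n_liit = 3, seed = 21,
                         consolidation_gain = 0, retention_offset = 10)
  t0 <- simulate_study(cfg0)
  t10 <- simulate_study(cfg10)
  idx <- t0$session %in% c("R24", "R7") & t0$group == "HIIT"
  expect_equal(t10$pitch_accuracy[idx],
               pmin(t0$pitch_accuracy[idx] + 10, 100))
  # LIIT rows and other sessions untouched
  expect_equal(t10$pitch_accuracy[!idx], t0$pitch_accuracy[!idx])
})

test_that("summaries produce one row per participant and session/block", {
  tr <- simulate_study(cohort_config(n_hiit = 3, n_liit = 3, seed = 31))
  sess <- summarize_sessions(tr)
  expect_identical(nrow(sess), 6L * 4L)
  expect_true(all(table(sess$participant_id) == 4))
  blocks <- summarize_blocks(tr)
  tran <- blocks[blocks$phase == "transfer", ]
  expect_identical(nrow(tran), 6L * 6L)
})
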