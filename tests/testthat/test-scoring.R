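test_that("identity and empty matches behave as expected", {
  m <- study_melody(1)
  id <- match_pitches(m$pitches, m$pitches)
  expect_identical(id$perf_index, 1:12)
  expect_identical(id$target_index, 1:12)
  expect_identical(nrow(match_pitches(integer(0), m$pitches)), 0L)
  expect_identical(nrow(match_pitches(m$pitches, integer(0))), 0L)
})

test_that("matcher cardinality equals the exhaustive enumeration oracle", {
  withr::local_seed(101)
  alphabet <- pitch_to_midi(c("A4", "B4", "C5", "D5", "E5"))
  for (i in 1:300) {
    a <- sample(alphabet, sample(0:8, 1), replace = TRUE)
    b <- sample(alphabet, sample(1:8, 1), replace = TRUE)
    mm <- match_pitches(a, b)
    expect_identical(nrow(mm), oracle_lcs_length(a, b),
                     info = paste("a =", paste(a, collapse = ","),
                                  "b =", paste(b, collapse = ",")))
    # validity of the alignment itself
    if (nrow(mm)) {
      expect_true(all(diff(mm$perf_index) > 0))
      expect_true(all(diff(mm$target_index) > 0))
      expect_identical(a[mm$perf_index], b[mm$target_index])
    }
  }
})

test_that("leftmost tie-break picks earliest performance then target indices", {
  # two equal-cardinality matchings exist; leftmost must take perf index 1
  mm <- match_pitches(c(69L, 69L), c(69L))
  expect_identical(mm$perf_index, 1L)
  mm2 <- match_pitches(c(69L), c(69L, 69L))
  expect_identical(mm2$target_index, 1L)
})

test_that("pitch accuracy uses the longer-sequence denominator", {
  m <- study_melody(1)
  # perfect rendition
  expect_equal(pitch_accuracy(match_pitches(m$pitches, m$pitches), 12, 12), 100)
  # 12 correct notes embedded in 24 performed notes -> 50
  doubled <- as.integer(rbind(m$pitches, rev(m$pitches)))
  mm <- match_pitches(doubled, m$pitches)
  expect_gte(nrow(mm), 12L)
  expect_equal(100 * 12 / max(12, 24), 50)
  # 10 matched of 12, 11 performed -> 83.33
  expect_equal(pitch_accuracy(structure(list(perf_index = 1:10,
                                             target_index = 1:10),
                                        class = "data.frame",
                                        row.names = 1:10), 12, 11),
               100 * 10 / 12)
  expect_error(pitch_accuracy(mm, 0, 5), "n_target")
})

test_that("rhythm accuracy follows the preceding-correct-note rule", {
  m <- study_melody(1)
  on <- melody_onsets(m)
  # metronomically perfect
  expect_equal(rhythm_accuracy(performance(m$pitches, on), m), 100)
  # every IOI stretched 15 percent: all intervals fail
  expect_equal(rhythm_accuracy(performance(m$pitches, on * 1.15), m), 0)
  # exactly one IOI stretched 15 percent: 10/11 (the interval into the
  # deviant note fails; the next interval is referenced to the preceding
  # matched note and passes)
  on2 <- on
  on2[6:12] <- on2[6:12] + 0.15 * (on[6] - on[5])
  expect_equal(rhythm_accuracy(performance(m$pitches, on2), m),
               100 * 10 / 11, tolerance = 1e-9)
  # boundary inclusive: a single IOI exactly 10 percent long still counts
  on3 <- on
  on3[2:12] <- on3[2:12] + 0.10 * (on[2] - on[1])
  expect_equal(rhythm_accuracy(performance(m$pitches, on3), m, tol = 0.10), 100)
})

test_that("empty and single-note performances score zero rhythm", {
  m <- study_melody(1)
  expect_equal(rhythm_accuracy(performance(), m), 0)
  expect_equal(rhythm_accuracy(performance(69L, 0), m), 0)
  s <- score_trial(performance(), m)
  expect_equal(s$pitch_accuracy, 0)
  expect_equal(s$rhythm_accuracy, 0)
})

test_that("an inconsistent match is rejected", {
  m <- study_melody(1)
  p <- performance(m$pitches, melody_onsets(m))
  bad <- structure(list(perf_index = 1L, target_index = 2L),
                   class = c("pitch_match", "data.frame"), row.names = 1L)
  expect_error(rhythm_accuracy(p, m, match = bad), "inconsistent")
})

test_that("rhythm accuracy is monotone in the tolerance", {
  withr::local_seed(7)
  m <- study_melody(1)
  for (i in 1:20) {
    p <- simulate_trial(learner_params(p0 = 0.8, asymptote = 0.8,
                                       timing_cv0 = 0.12,
                                       timing_cv_floor = 0.12), 1, m)
    tols <- c(0.02, 0.05, 0.10, 0.20, 0.30)
    accs <- vapply(tols, function(tl) rhythm_accuracy(p, m, tol = tl), 0)
    expect_true(all(diff(accs) >= 0))
  }
})

test_that("translation invariance holds with the always-correct first-note rule", {
  withr::local_seed(8)
  m <- study_melody(1)
  p <- simulate_trial(learner_params(p0 = 0.7, asymptote = 0.7), 1, m)
  shifted <- performance(p$events$pitch, p$events$onset + 1.7)
  expect_equal(rhythm_accuracy(shifted, m, first_note = "always"),
               rhythm_accuracy(p, m, first_note = "always"))
  s1 <- score_trial(p, m)
  s2 <- score_trial(shifted, m)
  expect_equal(s2$pitch_accuracy, s1$pitch_accuracy)
})

test_that("a first matched note after a wrong opening is judged on the grid", {
  m <- study_melody(1)
  on <- melody_onsets(m)
  wrong_first <- m$pitches
  wrong_first[1] <- pitch_to_midi("G4") # not in the target: cannot re-match
  # remaining notes on the exact grid: all 11 judgments pass (note 2 vs grid)
  expect_equal(rhythm_accuracy(performance(wrong_first, on), m), 100)
  # shift the whole performance late by 30 percent of the first IOI:
  # under the grid rule the first matched note's judgment now fails
  r_grid <- rhythm_accuracy(performance(wrong_first, on + 0.3 * on[2]), m)
  expect_equal(r_grid, 100 * 10 / 11, tolerance = 1e-9)
  r_always <- rhythm_accuracy(performance(wrong_first, on + 0.3 * on[2]), m,
                              first_note = "always")
  expect_equal(r_always, 100)
})

test_that("uniform-tempo renditions are perfect exactly within the tempo range", {
  m <- study_melody(1)
  for (tol in c(0.10, 0.30)) {
    lo <- 75 / (1 + tol)
    hi <- 75 / (1 - tol)
    for (bpm in c(lo + 0.01, 75, hi - 0.01)) {
      expect_equal(rhythm_accuracy(uniform_tempo_perf(m, bpm), m, tol = tol),
                   100, info = paste(tol, bpm))
    }
    for (bpm in c(lo - 0.5, hi + 0.5)) {
      expect_lt(rhythm_accuracy(uniform_tempo_perf(m, bpm), m, tol = tol), 100)
    }
  }
})

test_that("acceptable tempo ranges match the tolerance arithmetic", {
  expect_identical(unname(acceptable_tempo_range(75, 0.10)), c(68L, 83L))
  expect_identical(unname(acceptable_tempo_range(75, 0.30)), c(58L, 107L))
  expect_identical(unname(acceptable_tempo_range(75, 0)), c(75L, 75L))
  r <- acceptable_tempo_range(120, 0.10)
  expect_true(r[1] <= 120 && 120 <= r[2])
  expect_error(acceptable_tempo_range(75, 1), "tolerance")
  expect_error(acceptable_tempo_range(0, 0.1), "tempo")
})

test_that("score_trial composes the measures on a hand-worked toy case", {
  # 8-note toy melody, one substitution, exact timing
  toy <- melody_from_spec(c("A4", "B4", "C5", "D5", "E5", "D5", "C5", "B4"),
                          rep(1, 8), 75)
  perf_p <- toy$pitches
  perf_p[4] <- pitch_to_midi("A4")
  s <- score_trial(performance(perf_p, melody_onsets(toy)), toy)
  expect_equal(s$pitch_accuracy, 100 * 7 / 8)
  # matched notes 1-3 and 5-8 sit on the exact grid; the interval spanning
  # the substituted note (3 -> 5) covers two expected IOIs and passes too
  expect_equal(s$rhythm_accuracy, 100 * 6 / 7)
  expect_identical(s$n_correct_notes, 7L)
  expect_identical(s$n_target, 8L)
})

test_that("rhythm tolerance constructor validates its fraction", {
  expect_error(rhythm_tolerance(1.2), "fraction")
  expect_equal(rhythm_tolerance()$fraction, 0.10)
  expect_equal(rhythm_tolerance()$legacy_fraction, 0.30)
})
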