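test_that("GXT schedules start by sex and climb 30 W per stage", {
  expect_equal(build_gxt_schedule("F", 3)$power_w, c(50, 80, 110))
  expect_equal(build_gxt_schedule("M", 1)$power_w, 100)
  expect_equal(build_gxt_schedule("M", 5)$power_w, c(100, 130, 160, 190, 220))
  expect_true(all(build_gxt_schedule("F", 4)$planned_duration_s == 120))
  expect_error(build_gxt_schedule("X", 3), "sex")
  expect_error(build_gxt_schedule("M", 0), "n_stages")
})

test_that("W_max is the power of the last fully completed stage", {
  st <- build_gxt_schedule("F", 3)
  st$completed <- c(TRUE, TRUE, FALSE)
  expect_equal(wmax_from_stages(st), 80)
  st2 <- build_gxt_schedule("M", 5)
  st2$completed <- TRUE
  expect_equal(wmax_from_stages(st2), 220)
  st$completed <- FALSE
  expect_error(wmax_from_stages(st), "not scorable")
  # the 230 W female W_max in the participant table implies 7 completed
  # stages on the 50 + 30k grid
  st7 <- build_gxt_schedule("F", 7)
  st7$completed <- TRUE
  expect_equal(wmax_from_stages(st7), 230)
})

test_that("every packaged W_max lies on the sex-specific power lattices", {
  t1 <- load_table1()
  lattice <- c(100 + 30 * 0:7, 50 + 30 * 0:7)
  expect_true(all(t1$wmax %in% lattice))
})

test_that("VO2peak attainment flags follow the stated criteria", {
  expect_true(suppressWarnings(vo2peak_attained(rer_max = 1.12))$attained)
  res <- suppressWarnings(vo2peak_attained(rer_max = 1.12))
  expect_true(res$flags[["rer_gt_1.1"]])
  # strict boundary: RER exactly 1.1 does not qualify
  expect_false(suppressWarnings(vo2peak_attained(rer_max = 1.10))$attained)
  # HR plateau with sub-threshold RER
  st <- data.frame(power = c(100, 130, 160), hr = c(150, 170, 172),
                   vo2 = c(30, 35, 40))
  res2 <- suppressWarnings(vo2peak_attained(st, rer_max = 1.05))
  expect_true(res2$attained)
  expect_true(res2$flags[["vo2_or_hr_plateau"]])
  # rising HR and VO2, low RER, nothing else: not attained
  st3 <- data.frame(power = c(100, 130), hr = c(150, 170), vo2 = c(30, 35))
  expect_false(suppressWarnings(vo2peak_attained(st3, rer_max = 1.0))$attained)
  # cadence failure and volitional exhaustion each suffice
  expect_true(suppressWarnings(vo2peak_attained(cadence_ok = FALSE))$attained)
  expect_true(suppressWarnings(vo2peak_attained(volitional_exhaustion = TRUE))$attained)
  expect_warning(vo2peak_attained(rer_max = 1.0), "plateau criterion skipped")
})

test_that("interval protocols have the printed structure for both groups", {
  for (wmax in c(80, 100, 140, 200, 230)) {
    for (grp in c("HIIT", "LIIT")) {
      pr <- build_interval_protocol(wmax, grp)
      expect_equal(attr(pr, "total_duration_s"), 1140) # 19 min
      expect_equal(sum(pr$duration_s), 1140)
      expect_identical(pr$phase,
                       c("warmup", rep(c("low", "high"), 3), "cooldown"))
      expect_equal(pr$duration_s, c(120, rep(c(120, 180), 3), 120))
      fr <- if (grp == "HIIT") c(0.60, 0.90) else c(0.08, 0.12)
      expect_equal(unique(pr$intensity_fraction[pr$phase == "low"]), fr[1])
      expect_equal(unique(pr$intensity_fraction[pr$phase == "high"]), fr[2])
      expect_equal(unique(pr$intensity_fraction[pr$phase %in% c("warmup", "cooldown")]), 0.05)
      expect_equal(pr$power_w, pr$intensity_fraction * wmax)
      # identical 2:3 low:high intensity ratio in both groups
      expect_equal(fr[1] / fr[2], 2 / 3)
    }
  }
  pr <- build_interval_protocol(200, "HIIT")
  expect_equal(unique(pr$power_w[pr$phase == "high"]), 180)
  expect_equal(unique(pr$power_w[pr$phase == "low"]), 120)
  expect_equal(unique(pr$power_w[pr$phase == "warmup"]), 10)
  pr2 <- build_interval_protocol(100, "LIIT")
  expect_equal(unique(pr2$power_w[pr2$phase == "low"]), 8)
  expect_equal(unique(pr2$power_w[pr2$phase == "high"]), 12)
  expect_error(build_interval_protocol(0, "HIIT"), "positive")
})

test_that("high-intensity dose sums elapsed time in high segments", {
  pr <- build_interval_protocol(150, "HIIT")
  log_full <- data.frame(phase = pr$phase, planned_s = pr$duration_s,
                         elapsed_s = pr$duration_s)
  expect_equal(hiit_dose_completed(log_full)$label, "9 m 0 s")
  # stop 30 s into the first high interval
  log_stop <- log_full
  log_stop$elapsed_s <- c(120, 120, 30, 0, 0, 0, 0, 0)
  expect_equal(hiit_dose_completed(log_stop)$seconds, 30)
  expect_equal(hiit_dose_completed(log_stop)$label, "0 m 30 s")
  # a log reproducing the 4-minute abandonment point
  log_p20 <- log_full
  log_p20$elapsed_s <- c(120, 120, 180, 120, 60, 0, 0, 0)
  expect_equal(hiit_dose_completed(log_p20)$label, "4 m 0 s")
  # elapsed beyond plan is inconsistent
  log_bad <- log_full
  log_bad$elapsed_s[3] <- 999
  expect_error(hiit_dose_completed(log_bad), "exceeds planned")
})

test_that("dose labels parse and the packaged dose table loads", {
  expect_equal(parse_dose_label(c("10 m 30 s", "4 m", "15 m 45 s", "11 m")),
               c(630, 240, 945, 660))
  expect_error(parse_dose_label("ten minutes"), "unparseable")
  t2 <- load_table2()
  expect_identical(t2$pt, c(16L, 17L, 20L, 21L, 24L))
  expect_equal(t2$dose_s[t2$pt == 20], 240)
  # doses above 9 min occur and are accepted at face value
  expect_true(any(t2$dose_s > 540))
})
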