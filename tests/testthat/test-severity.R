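test_that("calibration anchors the target boundary at BKS 26 / UPDRS 35", {
  expect_equal(bks_to_severity(26), 2.5)
  expect_equal(severity_to_updrs(2.5), 35)
  expect_equal(bks_to_severity(23), 2.26)
  # below the lowest anchor clips into the level-0 region
  expect_equal(bks_to_severity(-5), 0)
  expect_equal(bks_to_severity(200), 5.5)
  expect_error(severity_calibration(bks = c(0, 10, 5),
                                    level = c(0, 1, 2)), "increasing")
})

test_that("severity mapping is monotone and matches the interpolation oracle", {
  cal <- severity_calibration()
  set.seed(21)
  b <- sort(runif(200, -10, 100))
  s <- bks_to_severity(b, cal)
  expect_true(all(diff(s) >= 0))
  expect_true(all(diff(severity_to_updrs(s)) >= 0))
  oracle <- pmin(pmax(approx(cal$bks, cal$level, xout = b, rule = 2)$y, 0), 5.5)
  expect_equal(s, oracle)
  # inverse calibration round trips inside the anchored range
  s_in <- runif(50, 0, 5.5)
  expect_equal(bks_to_severity(severity_to_bks(s_in, cal), cal), s_in)
})

test_that("integer levels bin the UPDRS equivalent with lower-closed edges", {
  # severity k+-0.5 are the level boundaries: [2.5, 3.5) -> level 3
  expect_equal(severity_level(c(0, 0.49, 0.5, 1.49, 2.49, 2.5, 3.49, 3.5,
                                4.49, 4.5, 5.5)),
               c(0L, 0L, 1L, 1L, 2L, 3L, 3L, 4L, 4L, 5L, 5L))
  # level 3 midpoint maps inside the published 35-47.5 interval
  expect_equal(severity_to_updrs(3), 41.25)
  # "severity >= 2.5" and "level in 3,4,5" coincide
  s <- seq(0, 5.5, by = 0.01)
  expect_equal(severity_level(s) >= 3L, s >= 2.5)
})

test_that("PTB counts levels 3-5 over active-available epochs", {
  prof_hi <- data.frame(severity = rep(5, 10), level = rep(5L, 10))
  m <- data.frame(active_available = rep(TRUE, 10))
  expect_equal(ptb(prof_hi, m), 100)
  prof_lo <- data.frame(severity = rep(0.2, 10), level = rep(0L, 10))
  expect_equal(ptb(prof_lo, m), 0)

  # 81 of 270 above target sits exactly on the 30% normal-range boundary
  lev <- c(rep(4L, 81), rep(1L, 189))
  prof <- data.frame(severity = ifelse(lev >= 3, 4, 1), level = lev)
  m270 <- data.frame(active_available = rep(TRUE, 270))
  expect_equal(ptb(prof, m270), 30)
  expect_equal(ptb_category(30), "intermediate")

  expect_true(is.na(ptb(prof, data.frame(active_available = rep(FALSE, 270)))))
})

test_that("per-level percents partition 100 and levels 3-5 sum to PTB", {
  # constructed mixture: 20/30/50% of available time in levels 3/4/5
  lev <- rep(c(3L, 4L, 5L), times = c(54, 81, 135))
  prof <- data.frame(severity = lev, level = lev)
  m <- data.frame(active_available = rep(TRUE, 270))
  pct <- percent_time_in_level(prof, m, 0:5)
  expect_equal(unname(pct[c("level_3", "level_4", "level_5")]),
               c(20, 30, 50))
  expect_equal(sum(pct), 100)
  expect_equal(unname(sum(pct[4:6])), ptb(prof, m))

  set.seed(31)
  lev2 <- sample(0:5, 400, replace = TRUE)
  prof2 <- data.frame(severity = lev2, level = as.integer(lev2))
  m2 <- data.frame(active_available = runif(400) < 0.8)
  expect_equal(sum(percent_time_in_level(prof2, m2, 0:5)), 100)
})

test_that("PTB is monotone under uniform score inflation (fixed masks)", {
  set.seed(41)
  rec <- make_recording(runif(300, 5, 60))
  masks <- epoch_masks(rec)
  cfg <- fluct_config()
  ptbs <- vapply(c(0, 2, 5, 10, 20), function(shift) {
    shifted <- rec
    shifted$epochs$bks <- rec$epochs$bks + shift
    ptb(severity_profile(shifted, cfg), masks)
  }, numeric(1))
  expect_true(all(diff(ptbs) >= 0))
})

test_that("PTB categories use the <30 / 30-75 / >=75 bins", {
  expect_equal(ptb_category(c(0, 29.9, 30, 74.9, 75, 100)),
               c("normal", "normal", "intermediate", "intermediate",
                 "high", "high"))
})

test_that("minutes conversion is 7.714 min per point above 30%", {
  expect_equal(ptb_to_minutes(53), 23 * 7.714)
  expect_equal(ptb_to_minutes(c(0, 10, 30)), c(0, 0, 0))
  expect_equal(ptb_to_minutes(100), 70 * 7.714) # ~ the full 9-h day
  expect_lt(abs(ptb_to_minutes(100) - 540), 0.1)
  expect_error(ptb_to_minutes(101), "out of")
  # continuous and piecewise linear across the knee
  expect_lt(ptb_to_minutes(30 + 1e-9), 1e-6)
})

test_that("referenced improvement rescales change to the attainable range", {
  expect_equal(referenced_improvement(63, 50, 30), 100 * 13 / 33)
  expect_equal(referenced_improvement(63, 50, 0), 100 * 13 / 63)
  expect_equal(referenced_improvement(40, 40, 30), 0)
  expect_error(referenced_improvement(25, 20, 30), "exceed")
})
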