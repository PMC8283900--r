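# severity-of-minute helpers: wall-clock severity curves rendered to scores
sev_curve <- function(baseline, trough, dose_min = 420,
                      flat = c(50, 70), rise_to = NULL, rise_end = 130) {
  force(list(baseline, trough, dose_min, flat, rise_to, rise_end))
  function(mod) {
    s <- rep(baseline, length(mod))
    tau <- mod - dose_min
    down <- tau >= 20 & tau < flat[1]
    s[down] <- baseline - (baseline - trough) * (tau[down] - 20) / (flat[1] - 20)
    s[tau >= flat[1] & tau < flat[2]] <- trough
    after <- tau >= flat[2]
    if (is.null(rise_to)) {
      up <- after & tau < flat[2] + 40
      s[up] <- trough + (baseline - trough) * (tau[up] - flat[2]) / 40
    } else {
      up <- after & tau < rise_end
      s[up] <- trough + (rise_to - trough) * (tau[up] - flat[2]) /
        (rise_end - flat[2])
      s[after & tau >= rise_end] <- rise_to
    }
    night <- mod < 390 | mod >= 1350
    out <- severity_to_bks(s)
    out[night] <- 85
    out
  }
}

test_that("first dose window skips reminders before 05:00", {
  rec <- make_recording(rep(20, 10),
                        doses = make_doses(c("2024-03-04 04:30:00",
                                             "2024-03-04 07:00:00")))
  w <- first_dose_window(rec)
  expect_true(w$estimable)
  expect_equal(w$dose_min, 420)
  expect_equal(w$slots, 208:212) # 5 epochs centred on 07:00

  none <- make_recording(rep(20, 10))
  expect_false(first_dose_window(none)$estimable)

  # a reminder at exactly 05:00 anchors the window (at-or-after)
  five <- make_recording(rep(20, 10),
                         doses = make_doses("2024-03-04 05:00:00"))
  expect_equal(first_dose_window(five)$dose_min, 300)
})

test_that("EMB pools window slots across days with the 50% availability rule", {
  rec <- make_daily_recording(function(mod) {
    out <- severity_to_bks(rep(3, length(mod)))
    out[mod < 390 | mod >= 1350] <- 85
    out
  })
  e <- emb(rec)
  expect_true(e$estimable)
  expect_equal(e$severity, 3, tolerance = 1e-9)
  expect_equal(e$sd, 0)
  expect_true(e$present) # >= 2.5

  # knock out window slots: 15/30 available is still estimable...
  mod <- with(as.POSIXlt(rec$epochs$timestamp, tz = "UTC"),
              hour * 60 + min)
  day <- as.integer(as.Date(rec$epochs$timestamp)) -
    as.integer(as.Date("2024-03-04")) + 1L # recording day 1..6
  in_win <- mod %in% c(416, 418, 420, 422, 424)
  rec15 <- rec
  rec15$epochs$worn[in_win & day %in% 1:3] <- FALSE
  e15 <- emb(rec15)
  expect_true(e15$estimable)
  expect_equal(e15$available_frac, 0.5)

  # ...but 14/30 is not (more than half the slots unavailable)
  rec14 <- rec15
  rec14$epochs$worn[in_win & day == 4 & mod == 416] <- FALSE
  e14 <- emb(rec14)
  expect_false(e14$estimable)
  expect_true(is.na(e14$severity))
})

test_that("peak effect finds the smoothed severity minimum 46-90 min post-dose", {
  # plateau trough at severity 2.0 from +50 to +70 min
  rec <- make_daily_recording(sev_curve(3.6, 2))
  p <- peak_effect(rec, dose_min = 420)
  expect_true(p$estimable)
  expect_equal(p$offset_min, 50) # earliest offset of the tied minimum
  expect_equal(p$time_min, 470)
  expect_equal(p$severity, 2, tolerance = 1e-9)
  expect_equal(p$sd, 0) # identical days

  # flat severity: tie-break to the earliest offset of the search window
  flat <- make_daily_recording(function(mod) {
    out <- severity_to_bks(rep(3.2, length(mod)))
    out[mod < 390 | mod >= 1350] <- 85
    out
  })
  pf <- peak_effect(flat, dose_min = 420)
  expect_equal(pf$offset_min, 46)
  expect_equal(pf$severity, 3.2, tolerance = 1e-9)
})

test_that("levodopa response thresholds at 1.15 severity levels", {
  expect_equal(levodopa_response(3.6, 2)$delta1, 1.6)
  expect_true(levodopa_response(3.6, 2)$significant)
  expect_true(levodopa_response(3.15, 2)$significant)  # exactly 1.15
  expect_false(levodopa_response(3.1499, 2)$significant)
  lr <- levodopa_response(2, 2.3)
  expect_equal(lr$delta1, -0.3)
  expect_false(lr$significant)
})

test_that("excess variability requires both anchors above one level", {
  expect_true(excess_variability(1.2, 1.3))
  expect_false(excess_variability(1.2, 0.4))
  expect_false(excess_variability(0, 0))
  cfg_or <- fluct_config(variability_rule = "or")
  expect_true(excess_variability(1.2, 0.4, cfg_or))
})

test_that("wearing-off is a >= 1 level rise within 2 h of the peak effect", {
  rec_wo <- make_daily_recording(sev_curve(3.6, 2, rise_to = 3.2))
  fa <- assess_fluctuation(rec_wo)
  expect_equal(fa$delta2, 1.2, tolerance = 0.05)
  expect_true(fa$wearing_off)
  expect_equal(fa$fluct_class, "FC_WO")

  # a persisting response never rises back
  rec_p <- make_daily_recording(function(mod) {
    s <- ifelse(mod >= 440 & mod < 1350, 2, 3.6)
    out <- severity_to_bks(s)
    out[mod < 390 | mod >= 1350] <- 85
    out
  })
  fp <- assess_fluctuation(rec_p)
  expect_equal(fp$delta2, 0, tolerance = 0.05)
  expect_false(fp$wearing_off)

  # sub-threshold rise (0.9 levels) is not wearing-off
  rec_sub <- make_daily_recording(sev_curve(3.6, 2, rise_to = 2.9))
  fs <- assess_fluctuation(rec_sub)
  expect_equal(fs$delta2, 0.9, tolerance = 0.05)
  expect_false(fs$wearing_off)
  expect_equal(fs$fluct_class, "FC_P")
})

test_that("classification covers all six branches", {
  expect_equal(classify_fluctuator(0.4, 1, 0.8, NA), "NFC")
  expect_equal(classify_fluctuator(0.4, 3, 2.6, NA), "NFU")
  expect_equal(classify_fluctuator(2, 3.5, 1.5, FALSE), "FC_P")
  expect_equal(classify_fluctuator(2, 3.5, 1.5, TRUE), "FC_WO")
  expect_equal(classify_fluctuator(1.5, 4.5, 3, FALSE), "FU_P")
  expect_equal(classify_fluctuator(1.5, 4.5, 3, TRUE), "FU_WO")
  expect_equal(classify_fluctuator(2, 3.5, 1.5, TRUE, qc_excluded = TRUE),
               "excluded")
  expect_equal(classify_fluctuator(NA, 3, 2, TRUE), "not_estimable")
  expect_equal(classify_fluctuator(2, 3.5, 1.5, NA), "not_estimable")
})

test_that("every QC-passing estimable subject lands in exactly one class", {
  cohort <- simulate_cohort(12, scenario_library(), seed = 77)
  for (s in cohort$subjects) {
    fa <- assess_fluctuation(s$recording)
    expect_true(fa$fluct_class %in% c("NFC", "NFU", "FC_P", "FC_WO",
                                      "FU_P", "FU_WO", "excluded",
                                      "not_estimable"))
    if (!fa$qc_excluded && !is.na(fa$delta1)) {
      expect_true(fa$fluct_class %in% c("NFC", "NFU", "FC_P", "FC_WO",
                                        "FU_P", "FU_WO"))
    }
  }
})

test_that("classification ignores content outside the dose-response windows", {
  sim <- simulate_subject(scenario_library()$FU_WO, seed = 9)
  full <- assess_fluctuation(sim$recording)
  mod <- with(as.POSIXlt(sim$recording$epochs$timestamp, tz = "UTC"),
              hour * 60 + min)
  pruned <- sim$recording
  keep <- mod >= 300 & mod < 1380 # drop deep-night epochs
  pruned$epochs <- pruned$epochs[keep, ]
  got <- assess_fluctuation(pruned)
  expect_equal(got$fluct_class, full$fluct_class)
  expect_equal(got$delta1, full$delta1)
  expect_equal(got$delta2, full$delta2)
})

test_that("subjects without reminders or with empty windows degrade gracefully", {
  rec <- make_recording(rep(20, 100))
  fa <- assess_fluctuation(rec)
  expect_equal(fa$fluct_class, "not_estimable")
  expect_true(is.na(fa$delta1))
  row <- summarize_subject(rec)
  expect_equal(row$fluct_class, "not_estimable")
  expect_equal(nrow(row), 1L)
})
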