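# Synthetic cohort generator.
#
# Emulates multi-day 2-minute epoch recordings with a known dose-response
# geometry so every pipeline stage can be validated against ground truth:
# diurnal sleep (scores at the sleep level overnight), dose-locked severity
# responses with a linear rise to peak and optional exponential wearing-off
# decay, dyskinesia episodes coincident with the peak levodopa effect,
# optional inactivity bouts, and sporadic walking/tremor flags. Severity is
# rendered to device bradykinesia scores through the inverse calibration.

#' Subject scenario
#'
#' The generative parameters for one synthetic subject. Defaults describe a
#' 6-day recording with three daily dose reminders and a response that peaks
#' 60 min post-dose (inside the 46-90 min search window).
#'
#' @param true_class Intended fluctuator class, used to label the scenario
#'   and checked against the class implied by the parameters.
#' @param baseline_severity Severity level before the first dose acts.
#' @param response_amplitude Drop in severity at peak effect (the ground
#'   truth for Delta1); 0 for non-fluctuators.
#' @param response_onset_min,response_peak_min Minutes post-dose at which the
#'   response starts rising and reaches its peak; the peak must lie in
#'   46-90 min.
#' @param wearing_off Logical: does the response decay after the peak?
#' @param wearing_off_halftime_min Exponential decay half-time, minutes.
#' @param dose_times Character vector of "HH:MM" dose-reminder clock times.
#' @param wake_time,sleep_time "HH:MM" limits of the awake period; outside
#'   it the bradykinesia score sits at the sleep level.
#' @param noise_sd Gaussian epoch noise on severity, level units.
#' @param dysk_amplitude Dyskinesia score during the peak-effect plateau
#'   (dyskinesia is dose-locked: present while the response is within 0.3
#'   levels of its maximum effect).
#' @param walking_rate,tremor_rate Per-epoch probability of the respective
#'   flag while awake.
#' @param inactivity_daily_min Minutes per day of an injected early-afternoon
#'   inactivity bout (severity ~4.3, score ~48) to exercise the
#'   moving-median mask; 0 disables it.
#' @param days Number of recorded days.
#' @param seed Integer RNG seed for [simulate_subject()].
#' @return A list of class `"subject_scenario"`.
#' @export
subject_scenario <- function(true_class = "NFC",
                             baseline_severity = 1,
                             response_amplitude = 0,
                             response_onset_min = 20,
                             response_peak_min = 60,
                             wearing_off = FALSE,
                             wearing_off_halftime_min = 45,
                             dose_times = c("07:00", "12:00", "17:00"),
                             wake_time = "06:30",
                             sleep_time = "22:30",
                             noise_sd = 0.15,
                             dysk_amplitude = 0,
                             walking_rate = 0.03,
                             tremor_rate = 0.02,
                             inactivity_daily_min = 0,
                             days = 6,
                             seed = 1L) {
  sc <- list(
    true_class = true_class,
    baseline_severity = baseline_severity,
    response_amplitude = response_amplitude,
    response_onset_min = response_onset_min,
    response_peak_min = response_peak_min,
    wearing_off = wearing_off,
    wearing_off_halftime_min = wearing_off_halftime_min,
    dose_times = dose_times,
    wake_time = wake_time,
    sleep_time = sleep_time,
    noise_sd = noise_sd,
    dysk_amplitude = dysk_amplitude,
    walking_rate = walking_rate,
    tremor_rate = tremor_rate,
    inactivity_daily_min = inactivity_daily_min,
    days = as.integer(days),
    seed = as.integer(seed)
  )
  if (sc$response_peak_min < 46 || sc$response_peak_min > 90) {
    stop("'response_peak_min' must lie in [46, 90]", call. = FALSE)
  }
  if (sc$response_onset_min >= sc$response_peak_min) {
    stop("'response_onset_min' must precede 'response_peak_min'", call. = FALSE)
  }
  if (sc$noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  for (r in c(sc$walking_rate, sc$tremor_rate)) {
    if (r < 0 || r > 1) stop("flag rates must be probabilities", call. = FALSE)
  }
  if (sc$baseline_severity < 0 || sc$baseline_severity > 5.3) {
    stop("'baseline_severity' must lie in [0, 5.3]", call. = FALSE)
  }
  if (sc$response_amplitude < 0 ||
      sc$response_amplitude > sc$baseline_severity) {
    stop("'response_amplitude' must lie in [0, baseline_severity]",
         call. = FALSE)
  }
  if (sc$days < 1 || sc$days > 10) stop("'days' must be 1-10", call. = FALSE)
  structure(sc, class = "subject_scenario")
}

#' Canonical fluctuator scenarios
#'
#' One scenario per fluctuator class, matching the archetypal response
#' curves: non-fluctuators with flat severity in (NFC) or out of (NFU) the
#' target range; fluctuators whose response enters the controlled range
#' (FC_*) or stays above target (FU_*), each with a persisting (_P) or
#' wearing-off (_WO) response.
#'
#' @param noise_sd Epoch noise applied to every scenario.
#' @return Named list of [subject_scenario()] objects.
#' @export
scenario_library <- function(noise_sd = 0.15) {
  base <- function(...) subject_scenario(noise_sd = noise_sd, ...)
  list(
    NFC = base(true_class = "NFC", baseline_severity = 1,
               response_amplitude = 0),
    NFU = base(true_class = "NFU", baseline_severity = 3.5,
               response_amplitude = 0),
    FC_P = base(true_class = "FC_P", baseline_severity = 3.5,
                response_amplitude = 2, dysk_amplitude = 12),
    FC_WO = base(true_class = "FC_WO", baseline_severity = 3.5,
                 response_amplitude = 2, wearing_off = TRUE,
                 dysk_amplitude = 12),
    FU_P = base(true_class = "FU_P", baseline_severity = 4.5,
                response_amplitude = 1.5),
    FU_WO = base(true_class = "FU_WO", baseline_severity = 4.5,
                 response_amplitude = 1.5, wearing_off = TRUE)
  )
}

#' Simulate one subject
#'
#' Builds the deterministic severity trace implied by the scenario, adds
#' Gaussian epoch noise, renders bradykinesia scores through the inverse
#' calibration (scores at 85 while asleep), generates dose-locked dyskinesia
#' and sporadic flags, and returns the recording together with its ground
#' truth. Reproducible from the scenario seed.
#'
#' @param scenario A [subject_scenario()].
#' @param subject_id Identifier for the generated subject.
#' @param seed Overrides `scenario$seed` when non-`NULL`.
#' @param config A [fluct_config()] (supplies the calibration and the
#'   thresholds used to derive ground truth).
#' @return List with `recording` (a `pkg_recording`) and `truth` (list:
#'   `true_class`, `true_delta1`, `true_pte_offset_min`,
#'   `true_ptb_fraction`, `true_ptd_fraction`).
#' @export
simulate_subject <- function(scenario, subject_id = "sim01", seed = NULL,
                             config = fluct_config()) {
  stopifnot(inherits(scenario, "subject_scenario"))
  set.seed(seed %||% scenario$seed)
  sc <- scenario

  n_per_day <- 720L
  n <- sc$days * n_per_day
  t0 <- as.POSIXct("2024-03-04 00:00:00", tz = "UTC")
  ts <- t0 + 120 * (seq_len(n) - 1L)
  mod <- minute_of_day(ts)
  wake <- parse_clock(sc$wake_time)
  bed <- parse_clock(sc$sleep_time)
  awake <- mod >= wake & mod < bed
  dose_min <- vapply(sc$dose_times, parse_clock, numeric(1))

  # dose-locked response: max over doses of the per-dose shape
  shape <- rep(0, n)
  for (d in dose_min) {
    tau <- mod - d
    r <- rep(0, n)
    rising <- tau >= sc$response_onset_min & tau < sc$response_peak_min
    r[rising] <- (tau[rising] - sc$response_onset_min) /
      (sc$response_peak_min - sc$response_onset_min)
    after <- tau >= sc$response_peak_min
    r[after] <- if (sc$wearing_off) {
      2^(-(tau[after] - sc$response_peak_min) / sc$wearing_off_halftime_min)
    } else {
      1
    }
    shape <- pmax(shape, r)
  }
  sev_clean <- pmin(pmax(sc$baseline_severity - sc$response_amplitude * shape,
                         0.05), 5.3)

  if (sc$inactivity_daily_min > 0) {
    bout_start <- parse_clock("13:30")
    in_bout <- mod >= bout_start & mod < bout_start + sc$inactivity_daily_min
    sev_clean[in_bout] <- 4.3
  }

  sev <- pmin(pmax(sev_clean + rnorm(n, 0, sc$noise_sd), 0), 5.45)
  bks <- severity_to_bks(sev, config$calibration)
  bks[!awake] <- 85

  near_peak <- sc$response_amplitude > 0 &
    sc$response_amplitude * (1 - shape) <= 0.3
  dks_clean <- ifelse(awake & near_peak, sc$dysk_amplitude, 0.5)
  dks <- pmax(0, dks_clean + rnorm(n, 0, 10 * sc$noise_sd))
  walking <- awake & rbinom(n, 1, sc$walking_rate) == 1L
  tremor <- awake & rbinom(n, 1, sc$tremor_rate) == 1L

  epochs <- data.frame(
    subject_id = subject_id, timestamp = ts, bks = bks, dks = dks,
    worn = TRUE, tremor = tremor, walking = walking
  )
  dose_days <- rep(seq_len(sc$days) - 1L, each = length(dose_min))
  doses <- data.frame(
    subject_id = subject_id,
    reminder_time = t0 + 86400 * dose_days + 60 * rep(dose_min, sc$days),
    acknowledged = TRUE
  )
  recording <- new_recording(epochs, doses, subject_id)

  truth <- ground_truth(sc, recording, sev_clean, dks_clean, awake, mod,
                        walking, tremor, config)
  list(recording = recording, truth = truth)
}

#' Simulate a cohort
#'
#' Draws `n` subjects from a mix of scenarios with per-subject seeds derived
#' deterministically from `seed`, and returns recordings plus a ground-truth
#' manifest.
#'
#' @param n Number of subjects.
#' @param scenario_mix Named list of [subject_scenario()] objects (e.g.
#'   [scenario_library()]) or a single scenario; subjects are assigned
#'   round-robin across the mix.
#' @param seed Integer master seed.
#' @param config A [fluct_config()].
#' @return List with `subjects` (list of `simulate_subject()` results) and
#'   `manifest` (data frame: `subject_id`, `scenario`, `true_class`,
#'   `true_delta1`, `true_pte_offset_min`, `true_ptb_fraction`,
#'   `true_ptd_fraction`, `seed`).
#' @export
simulate_cohort <- function(n, scenario_mix = scenario_library(), seed = 1L,
                            config = fluct_config()) {
  if (inherits(scenario_mix, "subject_scenario")) {
    scenario_mix <- list(scenario = scenario_mix)
  }
  n <- as.integer(n)
  if (n == 0L) {
    return(list(subjects = list(),
                manifest = data.frame(subject_id = character(),
                                      scenario = character(),
                                      true_class = character(),
                                      true_delta1 = numeric(),
                                      true_pte_offset_min = numeric(),
                                      true_ptb_fraction = numeric(),
                                      true_ptd_fraction = numeric(),
                                      seed = integer())))
  }
  names_mix <- names(scenario_mix)
  subjects <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    which_sc <- names_mix[((i - 1L) %% length(scenario_mix)) + 1L]
    sub_seed <- (as.integer(seed) * 1009L + i * 7919L) %% 2147483587L + 1L
    id <- sprintf("sim%03d", i)
    subjects[[i]] <- simulate_subject(scenario_mix[[which_sc]], id,
                                      seed = sub_seed, config = config)
    tr <- subjects[[i]]$truth
    rows[[i]] <- data.frame(
      subject_id = id, scenario = which_sc, true_class = tr$true_class,
      true_delta1 = tr$true_delta1,
      true_pte_offset_min = tr$true_pte_offset_min,
      true_ptb_fraction = tr$true_ptb_fraction,
      true_ptd_fraction = tr$true_ptd_fraction,
      seed = sub_seed, stringsAsFactors = FALSE
    )
  }
  list(subjects = subjects, manifest = do.call(rbind, rows))
}

# Ground truth from the noiseless traces, using the same thresholds and
# masks the pipeline applies (availability from the noiseless scores).
ground_truth <- function(sc, recording, sev_clean, dks_clean, awake, mod,
                         walking, tremor, config) {
  implied <- classify_fluctuator(
    delta1 = sc$response_amplitude,
    emb_severity = sc$baseline_severity,
    pte_severity = sc$baseline_severity - sc$response_amplitude,
    wo = sc$wearing_off,
    qc_excluded = FALSE, config = config
  )
  if (!identical(implied, sc$true_class)) {
    stop("scenario labelled ", sc$true_class,
         " but its parameters imply class ", implied, call. = FALSE)
  }
  daytime <- mod >= config$day_start & mod < config$day_end
  bks_clean <- severity_to_bks(sev_clean, config$calibration)
  bks_clean[!awake] <- 85
  mm <- moving_median(ifelse(awake, bks_clean, NA_real_),
                      config$inactivity_window,
                      epoch_slots(recording$epochs$timestamp))
  inactive <- !is.na(mm) & mm > config$inactivity_threshold
  act_avail <- daytime & awake & bks_clean < config$sleep_bks & !inactive
  ptb_frac <- if (any(act_avail)) {
    mean(sev_clean[act_avail] >= config$target_level)
  } else {
    NA_real_
  }
  # simulated epochs are always worn, so both denominator conventions
  # reduce to the daytime epoch count
  qual <- daytime & dks_clean >= config$dks_threshold & !walking & !tremor
  ptd_frac <- if (any(daytime)) sum(qual) / sum(daytime) else NA_real_
  list(true_class = sc$true_class,
       true_delta1 = sc$response_amplitude,
       true_pte_offset_min = sc$response_peak_min,
       true_ptb_fraction = ptb_frac,
       true_ptd_fraction = ptd_frac)
}
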