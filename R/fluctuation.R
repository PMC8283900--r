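# First-dose levodopa response, wearing-off and fluctuator classification.
#
# The first dose reminder at-or-after 05:00 anchors two clock windows:
#   EMB  - early-morning bradykinesia: mean severity over the 5 epochs
#          (10 min) centred on the reminder, pooled over all recorded days;
#   PTE  - time of peak levodopa effect: the minimum of the smoothed pooled
#          severity-by-offset curve 46-90 min after the dose (the "peak" of
#          the response is the point of least bradykinesia).
# The levodopa response Delta1 = EMB - PTE severity is significant at >= 1.15
# levels; wearing-off is a rise Delta2 >= 1 level within 2 h of the PTE time.
# Recordings with severity SD > 1 at both anchor times are QC-excluded.
# Availability here means worn and not asleep; the daytime analysis window
# does not apply (the first dose usually precedes 09:00), and the inactivity
# filter is handled by the variability QC rather than by exclusion.

FLUCT_CLASSES <- c("NFC", "NFU", "FC_P", "FC_WO", "FU_P", "FU_WO",
                   "excluded", "not_estimable")

#' First-dose clock window
#'
#' The 5-epoch (10-min) window centred on the first dose reminder at or
#' after the earliest admissible clock time (default 05:00); reminders
#' earlier than that are skipped. The window is a clock window: the same
#' epoch slots are pooled from every recorded day.
#'
#' @param recording A `pkg_recording`.
#' @param config A [fluct_config()].
#' @return A list with `estimable` (logical), `dose_min` (minutes since
#'   midnight of the anchoring reminder) and `slots` (integer within-day
#'   epoch slots of the window), or `estimable = FALSE` when no admissible
#'   reminder exists.
#' @export
first_dose_window <- function(recording, config = fluct_config()) {
  times <- minute_of_day(recording$doses$reminder_time)
  times <- sort(unique(times[times >= config$first_dose_earliest]))
  if (length(times) == 0L) {
    return(list(estimable = FALSE, dose_min = NA_real_, slots = integer()))
  }
  dose_min <- times[1]
  centre <- as.integer(round(dose_min / 2))
  hw <- config$emb_halfwidth
  list(estimable = TRUE, dose_min = dose_min,
       slots = (centre - hw):(centre + hw))
}

#' Early-morning bradykinesia (EMB)
#'
#' Mean severity over the first-dose window slots across all recorded days,
#' with its standard deviation over the same values. Not estimable when more
#' than half of the window's epoch slots (5 x days) are unavailable.
#'
#' @inheritParams first_dose_window
#' @param window A [first_dose_window()]; computed if missing.
#' @return List with `estimable`, `severity`, `sd`, `available_frac`,
#'   `present` (severity at or above the target boundary).
#' @export
emb <- function(recording, config = fluct_config(),
                window = first_dose_window(recording, config)) {
  if (!window$estimable) {
    return(list(estimable = FALSE, severity = NA_real_, sd = NA_real_,
                available_frac = NA_real_, present = NA))
  }
  sm <- severity_matrix(recording, config)
  vals <- as.vector(sm$severity[, window$slots + 1L, drop = FALSE])
  frac <- mean(!is.na(vals))
  if (frac < config$min_available_frac) {
    return(list(estimable = FALSE, severity = NA_real_, sd = NA_real_,
                available_frac = frac, present = NA))
  }
  v <- vals[!is.na(vals)]
  sev <- mean(v)
  list(estimable = TRUE, severity = sev,
       sd = if (length(v) > 1L) sd(v) else NA_real_,
       available_frac = frac, present = sev >= config$target_level)
}

#' Peak levodopa effect (PTE)
#'
#' Pools severity at matching offsets from the first dose across all
#' recorded days (mean by offset, requiring a minimum number of contributing
#' days per offset), smooths the pooled curve with the centred moving
#' median, and locates the minimum smoothed severity -- the peak effect,
#' i.e. least bradykinesia -- within the post-dose search window (default
#' 46-90 min). Ties break to the earliest offset.
#'
#' @inheritParams first_dose_window
#' @param dose_min Clock time of the first dose in minutes since midnight
#'   (from [first_dose_window()]).
#' @return List with `estimable`, `offset_min` (minutes post-dose),
#'   `time_min` (clock minutes), `severity`, `sd` (across-day SD at the peak
#'   offset) and `curve` (data frame `offset_min`, `mean`, `smoothed`,
#'   `n_days` over the whole evaluated offset range).
#' @export
peak_effect <- function(recording, config = fluct_config(), dose_min) {
  curve <- dose_response_curve(recording, config, dose_min)
  win <- config$pte_window_min
  in_win <- which(curve$offset_min >= win[1] & curve$offset_min <= win[2] &
                    !is.na(curve$smoothed))
  if (length(in_win) == 0L) {
    return(list(estimable = FALSE, offset_min = NA_real_, time_min = NA_real_,
                severity = NA_real_, sd = NA_real_, curve = curve))
  }
  best <- in_win[which.min(curve$smoothed[in_win])]
  off <- curve$offset_min[best]
  sm <- severity_matrix(recording, config)
  slot <- as.integer(round(dose_min / 2)) + as.integer(off / 2)
  day_vals <- if (slot + 1L <= ncol(sm$severity)) {
    sm$severity[, slot + 1L]
  } else {
    numeric(0)
  }
  day_vals <- day_vals[!is.na(day_vals)]
  list(estimable = TRUE, offset_min = off, time_min = dose_min + off,
       severity = curve$smoothed[best],
       sd = if (length(day_vals) > 1L) sd(day_vals) else NA_real_,
       curve = curve)
}

#' Levodopa response
#'
#' `Delta1 = EMB severity - PTE severity`, significant at or above the
#' configured threshold (default 1.15 severity levels, ~14 UPDRS-III
#' points).
#'
#' @param emb_severity,pte_severity Severity levels at the two anchors.
#' @param config A [fluct_config()].
#' @return List with `delta1` and `significant`.
#' @export
levodopa_response <- function(emb_severity, pte_severity,
                              config = fluct_config()) {
  d <- emb_severity - pte_severity
  list(delta1 = d, significant = !is.na(d) & d >= config$response_threshold)
}

#' Excess-variability quality control
#'
#' A recording is excluded when the severity standard deviation exceeds one
#' severity level (strictly) at the first-dose time and at the peak-effect
#' time. The default combines the two anchors conjunctively (`"and"`); a
#' disjunctive reading is available via `variability_rule = "or"`. Missing
#' SDs count as not excessive.
#'
#' @param sd_dose,sd_pte Severity SDs at the two anchor times.
#' @param config A [fluct_config()].
#' @return Logical: `TRUE` when the recording should be excluded.
#' @export
excess_variability <- function(sd_dose, sd_pte, config = fluct_config()) {
  hi_dose <- !is.na(sd_dose) & sd_dose > config$variability_sd
  hi_pte <- !is.na(sd_pte) & sd_pte > config$variability_sd
  if (config$variability_rule == "and") hi_dose & hi_pte else hi_dose | hi_pte
}

#' Wearing-off
#'
#' `Delta2` is the maximum rise of the smoothed pooled severity above the
#' peak-effect severity over the window `(PTE, PTE + 2 h]`, truncated at the
#' next dose reminder if that comes first; wearing-off is a rise of at least
#' one severity level.
#'
#' @param curve Pooled dose-response curve from [peak_effect()].
#' @param pte_offset_min,pte_severity Peak-effect offset (minutes post-dose)
#'   and severity.
#' @param config A [fluct_config()].
#' @param cap_offset_min Offset of the next dose reminder (minutes after the
#'   first dose), or `Inf`.
#' @return List with `estimable`, `delta2` and `wearing_off`.
#' @export
wearing_off <- function(curve, pte_offset_min, pte_severity,
                        config = fluct_config(), cap_offset_min = Inf) {
  hi <- min(pte_offset_min + config$wearing_off_horizon_min, cap_offset_min)
  sel <- curve$offset_min > pte_offset_min & curve$offset_min <= hi &
    !is.na(curve$smoothed)
  if (!any(sel)) {
    return(list(estimable = FALSE, delta2 = NA_real_, wearing_off = NA))
  }
  d2 <- max(curve$smoothed[sel]) - pte_severity
  list(estimable = TRUE, delta2 = d2,
       wearing_off = d2 >= config$wearing_off_threshold)
}

#' Six-way fluctuator classification
#'
#' Fluctuators have a significant levodopa response (`Delta1 >= 1.15`);
#' non-fluctuators are split by whether early-morning severity is in the
#' controlled range (`NFC`) or not (`NFU`). Fluctuators are split by whether
#' the peak-effect severity enters the controlled range (`FC_*` vs `FU_*`)
#' and by wearing-off (`*_P` persisting vs `*_WO`).
#'
#' @param delta1 Levodopa response, severity levels.
#' @param emb_severity,pte_severity Severities at the two anchors.
#' @param wo Logical wearing-off flag (may be `NA` for non-fluctuators).
#' @param qc_excluded Logical excess-variability flag.
#' @param config A [fluct_config()].
#' @return One of `"NFC"`, `"NFU"`, `"FC_P"`, `"FC_WO"`, `"FU_P"`,
#'   `"FU_WO"`, `"excluded"`, `"not_estimable"`.
#' @export
classify_fluctuator <- function(delta1, emb_severity, pte_severity, wo,
                                qc_excluded = FALSE,
                                config = fluct_config()) {
  if (isTRUE(qc_excluded)) return("excluded")
  if (is.na(delta1) || is.na(emb_severity) || is.na(pte_severity)) {
    return("not_estimable")
  }
  tgt <- config$target_level
  if (delta1 < config$response_threshold) {
    if (emb_severity < tgt) "NFC" else "NFU"
  } else {
    if (is.na(wo)) return("not_estimable")
    base <- if (pte_severity < tgt) "FC" else "FU"
    paste0(base, if (wo) "_WO" else "_P")
  }
}

#' Full fluctuation assessment of one recording
#'
#' Runs the first-dose window, EMB, peak-effect, levodopa-response,
#' wearing-off and excess-variability steps and classifies the subject.
#'
#' @inheritParams first_dose_window
#' @return An object of class `"pkg_fluct_assessment"`: `first_dose_time`
#'   and `pte_time` ("HH:MM" or `NA`), `emb_severity`, `emb_sd`,
#'   `emb_present`, `pte_offset_min`, `pte_severity`, `pte_sd`, `delta1`,
#'   `significant_response`, `delta2`, `wearing_off`, `qc_excluded`,
#'   `fluct_class`.
#' @export
assess_fluctuation <- function(recording, config = fluct_config()) {
  out <- list(
    subject_id = recording$subject_id,
    first_dose_time = NA_character_, emb_severity = NA_real_,
    emb_sd = NA_real_, emb_present = NA, emb_available_frac = NA_real_,
    pte_time = NA_character_, pte_offset_min = NA_real_,
    pte_severity = NA_real_, pte_sd = NA_real_,
    delta1 = NA_real_, significant_response = NA,
    delta2 = NA_real_, wearing_off = NA,
    qc_excluded = FALSE, fluct_class = "not_estimable"
  )
  class(out) <- "pkg_fluct_assessment"

  win <- first_dose_window(recording, config)
  if (!win$estimable) return(out)
  out$first_dose_time <- format_clock(win$dose_min)

  e <- emb(recording, config, win)
  out$emb_severity <- e$severity
  out$emb_sd <- e$sd
  out$emb_present <- e$present
  out$emb_available_frac <- e$available_frac

  p <- peak_effect(recording, config, win$dose_min)
  if (p$estimable) {
    out$pte_time <- format_clock(p$time_min)
    out$pte_offset_min <- p$offset_min
    out$pte_severity <- p$severity
    out$pte_sd <- p$sd
  }
  if (!e$estimable || !p$estimable) return(out)

  lr <- levodopa_response(e$severity, p$severity, config)
  out$delta1 <- lr$delta1
  out$significant_response <- lr$significant

  cap <- next_dose_offset(recording, win$dose_min, config)
  wo <- wearing_off(p$curve, p$offset_min, p$severity, config, cap)
  out$delta2 <- wo$delta2
  out$wearing_off <- wo$wearing_off

  out$qc_excluded <- excess_variability(e$sd, p$sd, config)
  out$fluct_class <- classify_fluctuator(
    lr$delta1, e$severity, p$severity, wo$wearing_off, out$qc_excluded, config
  )
  out
}

#' @export
print.pkg_fluct_assessment <- function(x, ...) {
  cat(sprintf("<pkg_fluct_assessment> subject %s: class %s\n",
              x$subject_id, x$fluct_class))
  cat(sprintf("  first dose %s  EMB %.2f (sd %.2f)  PTE %s (+%g min) %.2f (sd %.2f)\n",
              x$first_dose_time, x$emb_severity, x$emb_sd, x$pte_time,
              x$pte_offset_min, x$pte_severity, x$pte_sd))
  cat(sprintf("  Delta1 %.2f (significant: %s)  Delta2 %.2f (wearing-off: %s)  QC excluded: %s\n",
              x$delta1, x$significant_response, x$delta2, x$wearing_off,
              x$qc_excluded))
  invisible(x)
}

#' One-row per-subject summary
#'
#' Combines [summary_scores()] and [assess_fluctuation()] into a single
#' data-frame row suitable for [write_summary()]. QC-excluded recordings
#' carry the class `"excluded_variability"` in the summary.
#'
#' @inheritParams first_dose_window
#' @return A one-row data frame.
#' @export
summarize_subject <- function(recording, config = fluct_config()) {
  sc <- summary_scores(recording, config)
  fa <- assess_fluctuation(recording, config)
  cls <- fa$fluct_class
  if (cls == "excluded") cls <- "excluded_variability"
  df <- data.frame(
    subject_id = recording$subject_id,
    mbks = sc$mbks, active_mbks = sc$active_mbks,
    mdks = sc$mdks, adjusted_mdks = sc$adjusted_mdks,
    ptb = sc$ptb, ptd = sc$ptd,
    ptb_minutes = sc$ptb_minutes, ptb_category = sc$ptb_category,
    first_dose_time = fa$first_dose_time,
    emb_severity = fa$emb_severity, emb_present = fa$emb_present,
    pte_time = fa$pte_time, pte_severity = fa$pte_severity,
    delta1 = fa$delta1, significant_response = fa$significant_response,
    delta2 = fa$delta2, wearing_off = fa$wearing_off,
    qc_excluded = fa$qc_excluded, fluct_class = cls,
    ledd = recording$ledd,
    stringsAsFactors = FALSE
  )
  for (l in 0:5) df[[paste0("pct_level_", l)]] <- unname(sc$pct_level[l + 1])
  df
}

# -- internals ---------------------------------------------------------------

# day x within-day-slot severity matrix (720 two-minute slots per day);
# NA where no epoch is present or the epoch is not worn / asleep.
severity_matrix <- function(recording, config) {
  ep <- recording$epochs
  s <- bks_to_severity(ep$bks, config$calibration)
  s[!ep$worn | is.na(ep$bks) | ep$bks >= config$sleep_bks] <- NA_real_
  days <- day_index(ep$timestamp)
  udays <- sort(unique(days))
  slot <- as.integer(floor(minute_of_day(ep$timestamp) / 2))
  mat <- matrix(NA_real_, nrow = length(udays), ncol = 720L)
  mat[cbind(match(days, udays), slot + 1L)] <- s
  list(severity = mat, days = udays)
}

# Pooled mean severity by offset from the dose, smoothed; evaluated from the
# dose out to the wearing-off horizon past the latest admissible peak time.
dose_response_curve <- function(recording, config, dose_min) {
  sm <- severity_matrix(recording, config)
  dose_slot <- as.integer(round(dose_min / 2))
  max_off_slot <- ceiling((config$pte_window_min[2] +
                             config$wearing_off_horizon_min) / 2) +
    (config$pte_smooth_window - 1L) / 2L
  offs <- 0:max_off_slot
  cols <- dose_slot + offs + 1L
  keep <- cols <= ncol(sm$severity)
  offs <- offs[keep]
  cols <- cols[keep]
  vals <- sm$severity[, cols, drop = FALSE]
  n_days <- colSums(!is.na(vals))
  mean_sev <- ifelse(n_days >= config$min_days_per_offset,
                     colMeans(vals, na.rm = TRUE), NA_real_)
  smoothed <- moving_median(mean_sev, config$pte_smooth_window, slots = offs)
  data.frame(offset_min = 2 * offs, mean = as.numeric(mean_sev),
             smoothed = smoothed, n_days = n_days)
}

# Offset (minutes after the first dose) of the next later dose reminder.
next_dose_offset <- function(recording, dose_min, config) {
  times <- sort(unique(minute_of_day(recording$doses$reminder_time)))
  later <- times[times > dose_min]
  if (length(later) == 0L) Inf else later[1] - dose_min
}
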