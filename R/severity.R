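# Severity-level calibration and the PTB family.
#
# Bradykinesia scores are mapped to a continuous 0-5.5 severity scale whose
# integer levels correspond to fixed UPDRS-III intervals:
#   level      0       1         2         3         4        5
#   UPDRS III  0-10    10-22.5   22.5-35   35-47.5   47.5-60  >= 60
# Severity 2.5 (BKS 26, UPDRS 35) is the in/out-of-target boundary; levels
# 3-5 are "above target" and define percent time in bradykinesia (PTB).

UPDRS_LEVEL_EDGES <- c(0, 10, 22.5, 35, 47.5, 60, Inf)

#' Bradykinesia-score to severity-level calibration
#'
#' A monotone piecewise-linear map between the device bradykinesia score and
#' the continuous severity level. Only the anchor BKS 26 -> level 2.5 (UPDRS
#' III 35) is fixed by the published target; the remaining default anchors
#' place the other published score boundaries (BKS 23 just inside target,
#' BKS >= 80 sleep) where the scale expects them, and are user-replaceable.
#'
#' @param bks,level Numeric vectors of equal length giving the anchor points;
#'   both must be strictly increasing.
#' @return A data frame of class `"severity_calibration"` with columns `bks`
#'   and `level`.
#' @export
#' @examples
#' cal <- severity_calibration()
#' bks_to_severity(26, cal) # 2.5, the target boundary
severity_calibration <- function(bks = c(0, 23, 26, 40, 80),
                                 level = c(0, 2.26, 2.5, 4, 5.5)) {
  if (length(bks) != length(level) || length(bks) < 2L) {
    stop("calibration needs >= 2 anchor pairs", call. = FALSE)
  }
  if (any(diff(bks) <= 0) || any(diff(level) <= 0)) {
    stop("calibration anchors must be strictly increasing in both bks and level",
         call. = FALSE)
  }
  structure(data.frame(bks = bks, level = level),
            class = c("severity_calibration", "data.frame"))
}

#' Map bradykinesia scores to continuous severity levels
#'
#' Piecewise-linear interpolation through the calibration anchors, constant
#' beyond the extreme anchors, clipped to `[0, 5.5]`.
#'
#' @param bks Numeric vector of bradykinesia scores.
#' @param calibration A [severity_calibration()].
#' @return Numeric vector of severity levels in `[0, 5.5]`; `NA` maps to `NA`.
#' @export
bks_to_severity <- function(bks, calibration = severity_calibration()) {
  stopifnot(inherits(calibration, "severity_calibration"))
  out <- rep(NA_real_, length(bks))
  ok <- !is.na(bks)
  if (any(ok)) {
    out[ok] <- approx(calibration$bks, calibration$level, xout = bks[ok],
                      rule = 2)$y
  }
  pmin(pmax(out, 0), 5.5)
}

#' Inverse calibration: severity level to bradykinesia score
#'
#' Used by the simulator to render a severity trace as device scores.
#'
#' @inheritParams bks_to_severity
#' @param level Numeric vector of severity levels.
#' @return Numeric vector of bradykinesia scores.
#' @export
severity_to_bks <- function(level, calibration = severity_calibration()) {
  stopifnot(inherits(calibration, "severity_calibration"))
  out <- rep(NA_real_, length(level))
  ok <- !is.na(level)
  if (any(ok)) {
    out[ok] <- approx(calibration$level, calibration$bks, xout = level[ok],
                      rule = 2)$y
  }
  out
}

#' UPDRS-III equivalent of a continuous severity level
#'
#' Linear at 12.5 UPDRS points per level, anchored so that level 2.5 maps to
#' UPDRS III 35; a response of 1.15 levels is therefore ~14 UPDRS points.
#'
#' @param level Numeric vector of severity levels.
#' @param config A [fluct_config()].
#' @return UPDRS-III-equivalent scores (floored at 0).
#' @export
#' @examples
#' severity_to_updrs(2.5)        # 35
#' 1.15 * 12.5                   # ~14-point levodopa response
severity_to_updrs <- function(level, config = fluct_config()) {
  pmax(0, config$updrs_at_target +
         (level - config$target_level) * config$updrs_per_level)
}

#' Integer severity level (0-5) of a continuous severity value
#'
#' Bins the UPDRS-III equivalent by the fixed interval edges, lower-closed,
#' so that "severity >= 2.5" and "level in 3,4,5" coincide exactly.
#'
#' @inheritParams severity_to_updrs
#' @return Integer vector with values 0-5 (`NA` preserved).
#' @export
severity_level <- function(level, config = fluct_config()) {
  updrs <- severity_to_updrs(level, config)
  out <- findInterval(updrs, UPDRS_LEVEL_EDGES[2:6])
  out[is.na(level)] <- NA_integer_
  as.integer(out)
}

#' Per-epoch severity profile of a recording
#'
#' @param recording A `pkg_recording`.
#' @param config A [fluct_config()].
#' @return Data frame with per-epoch `severity` (continuous), `level`
#'   (integer 0-5) and `above_target` (severity >= target boundary).
#'   Epochs that are not worn or are asleep get `NA`.
#' @export
severity_profile <- function(recording, config = fluct_config()) {
  ep <- recording$epochs
  s <- bks_to_severity(ep$bks, config$calibration)
  s[!ep$worn | ep$bks >= config$sleep_bks] <- NA_real_
  data.frame(
    severity = s,
    level = severity_level(s, config),
    above_target = s >= config$target_level
  )
}

#' Percent time in bradykinesia (PTB)
#'
#' The percentage of available epochs (worn, daytime, not sleep, not
#' inactive -- the same exclusions as the active median bradykinesia score)
#' whose severity level is 3, 4 or 5 (severity >= 2.5).
#'
#' @param profile A [severity_profile()] data frame.
#' @param masks An [epoch_masks()] data frame.
#' @return Percent in `[0, 100]`, or `NA` if no epoch is available.
#' @export
ptb <- function(profile, masks) {
  use <- masks$active_available & !is.na(profile$level)
  n <- sum(use)
  if (n == 0L) return(NA_real_)
  100 * sum(profile$level[use] >= 3L) / n
}

#' Percent time in a single severity level
#'
#' Same denominator as [ptb()]; the per-level percents partition 100% and
#' levels 3-5 sum to PTB.
#'
#' @inheritParams ptb
#' @param level Integer level 0-5, or a vector of levels.
#' @return Percent per requested level (named vector if several).
#' @export
percent_time_in_level <- function(profile, masks, level = 0:5) {
  use <- masks$active_available & !is.na(profile$level)
  n <- sum(use)
  out <- vapply(level, function(l) {
    if (n == 0L) NA_real_ else 100 * sum(profile$level[use] == l) / n
  }, numeric(1))
  names(out) <- paste0("level_", level)
  if (length(level) == 1L) unname(out) else out
}

#' PTB severity category
#'
#' Bins PTB into `normal` (< first boundary), `intermediate` and `high`
#' (>= second boundary); defaults 30% and 75%.
#'
#' @param ptb PTB values, percent.
#' @param config A [fluct_config()].
#' @return Character vector in `{"normal", "intermediate", "high"}`.
#' @export
ptb_category <- function(ptb, config = fluct_config()) {
  bins <- config$ptb_bins
  out <- ifelse(ptb < bins[1], "normal",
                ifelse(ptb < bins[2], "intermediate", "high"))
  out[is.na(ptb)] <- NA_character_
  out
}

#' Convert PTB to nominal minutes above target per 9-hour day
#'
#' `minutes = max(0, PTB - 30) * 7.714`, treating PTB below the control
#' upper limit as zero time above target. A PTB of 53% is nominally 3 of the
#' 9 available hours above target.
#'
#' @param ptb PTB values in `[0, 100]`, percent.
#' @param config A [fluct_config()].
#' @return Minutes above target per day.
#' @export
#' @examples
#' ptb_to_minutes(53) / 60  # ~3 hours
ptb_to_minutes <- function(ptb, config = fluct_config()) {
  bad <- !is.na(ptb) & (ptb < 0 | ptb > 100)
  if (any(bad)) {
    stop("ptb out of [0, 100]: ", paste(ptb[bad], collapse = ", "),
         call. = FALSE)
  }
  pmax(0, ptb - config$ptb_normal) * config$minutes_slope
}

#' Percent improvement referenced to a control boundary
#'
#' `100 * (before - after) / (before - reference)`. Referencing to the upper
#' limit of the control range (rather than to zero) expresses how much of the
#' attainable improvement was achieved: a PTB change 63% -> 50% is a 20.6%
#' raw change but a 39% improvement referenced to 30%.
#'
#' @param before,after Measure before and after treatment.
#' @param reference Reference level subtracted from both (default 0).
#' @return Percent improvement.
#' @export
#' @examples
#' referenced_improvement(63, 50, 30) # ~39
#' referenced_improvement(63, 50, 0)  # ~20.6
referenced_improvement <- function(before, after, reference = 0) {
  if (any(before <= reference)) {
    stop("'before' must exceed 'reference'", call. = FALSE)
  }
  100 * (before - after) / (before - reference)
}
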