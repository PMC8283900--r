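# The glossary's median-score family and percent time in dyskinesia.
#
# All medians are 50th percentiles with linear interpolation between order
# statistics (stats::quantile type 7), pooled over all recorded days inside
# the daytime window. "Not estimable" (no epoch survives masking) is NA.

#' Median bradykinesia score (mBKS)
#'
#' 50th percentile of the bradykinesia score over daytime epochs where the
#' logger was worn and the score is below the sleep threshold, pooled over
#' all recorded days.
#'
#' @param recording A `pkg_recording`.
#' @param masks An [epoch_masks()] data frame for the recording.
#' @return Score, or `NA` if no epoch is available.
#' @export
median_bks <- function(recording, masks) {
  x <- recording$epochs$bks[masks$available]
  percentile50(x)
}

#' Active median bradykinesia score
#'
#' As [median_bks()] but additionally removing inactivity epochs (30-min
#' moving median of the score above the inactivity threshold), so that
#' immobile periods do not inflate the estimate.
#'
#' @inheritParams median_bks
#' @return Score, or `NA` if no epoch is available.
#' @export
active_median_bks <- function(recording, masks) {
  x <- recording$epochs$bks[masks$active_available]
  percentile50(x)
}

#' Median dyskinesia score (mDKS)
#'
#' 50th percentile of the dyskinesia score over worn daytime epochs, pooled
#' over all recorded days.
#'
#' @inheritParams median_bks
#' @return Score, or `NA` if no epoch is available.
#' @export
median_dks <- function(recording, masks) {
  use <- masks$worn & masks$daytime
  percentile50(recording$epochs$dks[use])
}

#' Adjusted median dyskinesia score
#'
#' As [median_dks()] with two corrections: epochs in which walking was
#' detected are removed from the sample (walking energy contaminates the
#' dyskinesia signal), and epochs with detected tremor whose dyskinesia
#' score is at or above the dyskinesia threshold contribute a value of zero
#' (the elevated score is attributed to tremor rather than dyskinesia).
#'
#' @inheritParams median_bks
#' @param config A [fluct_config()] (supplies the dyskinesia threshold).
#' @return Score, or `NA` if no epoch is available.
#' @export
adjusted_median_dks <- function(recording, masks, config = fluct_config()) {
  ep <- recording$epochs
  use <- masks$worn & masks$daytime & !ep$walking
  dks <- ep$dks[use]
  zero <- ep$tremor[use] & !is.na(dks) & dks >= config$dks_threshold
  dks[zero] <- 0
  percentile50(dks)
}

#' Percent time in dyskinesia (PTD)
#'
#' Percentage of daytime epochs whose dyskinesia score is at or above the
#' threshold (default 10, the 75th percentile of a control population) and
#' in which neither walking nor tremor was detected. The denominator is all
#' worn daytime epochs by default (`ptd_denominator = "worn"`), or every
#' daytime epoch with `"all"`.
#'
#' @inheritParams adjusted_median_dks
#' @return Percent in `[0, 100]`, or `NA` with an empty denominator.
#' @export
ptd <- function(recording, masks, config = fluct_config()) {
  ep <- recording$epochs
  denom_mask <- if (config$ptd_denominator == "worn") {
    masks$worn & masks$daytime
  } else {
    masks$daytime
  }
  n <- sum(denom_mask)
  if (n == 0L) return(NA_real_)
  qual <- denom_mask & masks$worn & !is.na(ep$dks) &
    ep$dks >= config$dks_threshold & !ep$walking & !ep$tremor
  100 * sum(qual) / n
}

#' All summary scores for one recording
#'
#' @inheritParams adjusted_median_dks
#' @param masks Optional precomputed [epoch_masks()].
#' @return A list of class `"pkg_summary_scores"`: `mbks`, `active_mbks`,
#'   `mdks`, `adjusted_mdks`, `ptd`, `ptb`, `ptb_minutes`, `ptb_category`
#'   and `pct_level` (named percent per severity level 0-5).
#' @export
summary_scores <- function(recording, config = fluct_config(), masks = NULL) {
  masks <- masks %||% epoch_masks(recording, config)
  profile <- severity_profile(recording, config)
  ptb_val <- ptb(profile, masks)
  structure(list(
    mbks = median_bks(recording, masks),
    active_mbks = active_median_bks(recording, masks),
    mdks = median_dks(recording, masks),
    adjusted_mdks = adjusted_median_dks(recording, masks, config),
    ptd = ptd(recording, masks, config),
    ptb = ptb_val,
    ptb_minutes = if (is.na(ptb_val)) NA_real_ else
      ptb_to_minutes(ptb_val, config),
    ptb_category = ptb_category(ptb_val, config),
    pct_level = percent_time_in_level(profile, masks, 0:5)
  ), class = "pkg_summary_scores")
}

#' @export
print.pkg_summary_scores <- function(x, ...) {
  cat("<pkg_summary_scores>\n")
  cat(sprintf("  mBKS %.1f (active %.1f)  mDKS %.1f (adjusted %.1f)\n",
              x$mbks, x$active_mbks, x$mdks, x$adjusted_mdks))
  cat(sprintf("  PTB %.1f%% (%s; %.0f min/day above target)  PTD %.1f%%\n",
              x$ptb, x$ptb_category, x$ptb_minutes, x$ptd))
  cat("  % time per severity level:",
      paste(sprintf("%d: %.1f", 0:5, x$pct_level), collapse = "  "), "\n")
  invisible(x)
}

percentile50 <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  unname(quantile(x, 0.5, type = 7))
}
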