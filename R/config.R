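# Analysis thresholds. Every published constant lives here so that a study
# can swap the whole set from a YAML file.

#' Analysis configuration
#'
#' Collects every threshold used by the masking, scoring and fluctuation
#' modules. Defaults reproduce the published analysis settings; any value can
#' be overridden here or via [read_config()].
#'
#' @param day_start,day_end Daytime analysis window as "HH:MM" clock times;
#'   the window is half-open, `[day_start, day_end)`. Default 09:00-18:00
#'   (270 two-minute epochs per day).
#' @param sleep_bks Bradykinesia score at or above which an epoch is treated
#'   as sleep (score units; default 80).
#' @param inactivity_threshold Moving-median bradykinesia score above which
#'   (strictly) an epoch is inactive (default 40).
#' @param inactivity_window,median_window Moving-median window in epochs
#'   (odd; 15 epochs = 30 min).
#' @param pte_smooth_window Moving-median window, in epochs, applied to the
#'   pooled dose-response curve before locating the peak effect (default 7
#'   epochs = 14 min; the curve is already a mean over all recorded days, and
#'   a wide median flattens the response trough, attenuating the measured
#'   levodopa response and wearing-off).
#' @param dks_threshold Dyskinesia score at or above which an epoch counts as
#'   dyskinetic for PTD and for the tremor correction (default 10, the 75th
#'   percentile of a control population).
#' @param ptd_denominator `"worn"` (default) counts only worn daytime epochs
#'   in the PTD denominator; `"all"` counts every daytime epoch.
#' @param target_level In/out-of-target severity boundary (default 2.5).
#' @param response_threshold Minimum levodopa response Delta1, in severity
#'   levels, considered clinically significant (default 1.15).
#' @param wearing_off_threshold Minimum rise Delta2 from the peak-effect
#'   severity that counts as wearing-off (default 1 level).
#' @param wearing_off_horizon_min Horizon after the peak-effect time searched
#'   for wearing-off, minutes (default 120).
#' @param pte_window_min Two-element vector: offsets after the first dose, in
#'   minutes, searched for the peak levodopa effect (default c(46, 90)).
#' @param first_dose_earliest Earliest clock time a dose reminder may anchor
#'   the first-dose window ("HH:MM"; default "05:00").
#' @param emb_halfwidth Half-width, in epochs, of the first-dose window
#'   (default 2, i.e. 5 epochs / 10 min).
#' @param min_available_frac Minimum fraction of first-dose window slots that
#'   must be available for early-morning bradykinesia to be estimated
#'   (default 0.5).
#' @param variability_sd Severity-level standard deviation above which
#'   (strictly) variability at an anchor time is excessive (default 1).
#' @param variability_rule `"and"` (default) excludes a recording when both
#'   anchor SDs are excessive; `"or"` when either is.
#' @param min_days_per_offset Minimum number of days that must contribute to
#'   a pooled dose-response offset (default 3).
#' @param ptb_normal,ptd_normal Upper limits of the control range for PTB and
#'   PTD, percent (defaults 30 and 20).
#' @param ptb_bins Boundaries of the PTB categories
#'   normal / intermediate / high (default c(30, 75)).
#' @param minutes_slope Minutes above target per PTB percentage point beyond
#'   `ptb_normal` over a 9-h day (default 7.714).
#' @param updrs_per_level UPDRS-III points per severity level (default 12.5).
#' @param updrs_at_target UPDRS-III equivalent of the target boundary
#'   severity (default 35 at level 2.5).
#' @param calibration A [severity_calibration()] table.
#'
#' @return A list of class `"fluct_config"`.
#' @seealso [read_config()], [severity_calibration()]
#' @export
#' @examples
#' cfg <- fluct_config()
#' cfg$response_threshold
fluct_config <- function(day_start = "09:00",
                         day_end = "18:00",
                         sleep_bks = 80,
                         inactivity_threshold = 40,
                         inactivity_window = 15,
                         median_window = 15,
                         pte_smooth_window = 7,
                         dks_threshold = 10,
                         ptd_denominator = c("worn", "all"),
                         target_level = 2.5,
                         response_threshold = 1.15,
                         wearing_off_threshold = 1,
                         wearing_off_horizon_min = 120,
                         pte_window_min = c(46, 90),
                         first_dose_earliest = "05:00",
                         emb_halfwidth = 2,
                         min_available_frac = 0.5,
                         variability_sd = 1,
                         variability_rule = c("and", "or"),
                         min_days_per_offset = 3,
                         ptb_normal = 30,
                         ptd_normal = 20,
                         ptb_bins = c(30, 75),
                         minutes_slope = 7.714,
                         updrs_per_level = 12.5,
                         updrs_at_target = 35,
                         calibration = severity_calibration()) {
  ptd_denominator <- match.arg(ptd_denominator)
  variability_rule <- match.arg(variability_rule)
  for (w in c(inactivity_window, median_window, pte_smooth_window)) {
    if (w < 3 || w %% 2 == 0) {
      stop("moving-median windows must be odd integers >= 3, got ", w,
           call. = FALSE)
    }
  }
  if (length(pte_window_min) != 2L || pte_window_min[1] > pte_window_min[2]) {
    stop("'pte_window_min' must be c(lo, hi) with lo <= hi", call. = FALSE)
  }
  if (length(ptb_bins) != 2L || ptb_bins[1] >= ptb_bins[2]) {
    stop("'ptb_bins' must be two increasing boundaries", call. = FALSE)
  }
  cfg <- list(
    day_start = parse_clock(day_start),
    day_end = parse_clock(day_end),
    sleep_bks = sleep_bks,
    inactivity_threshold = inactivity_threshold,
    inactivity_window = as.integer(inactivity_window),
    median_window = as.integer(median_window),
    pte_smooth_window = as.integer(pte_smooth_window),
    dks_threshold = dks_threshold,
    ptd_denominator = ptd_denominator,
    target_level = target_level,
    response_threshold = response_threshold,
    wearing_off_threshold = wearing_off_threshold,
    wearing_off_horizon_min = wearing_off_horizon_min,
    pte_window_min = pte_window_min,
    first_dose_earliest = parse_clock(first_dose_earliest),
    emb_halfwidth = as.integer(emb_halfwidth),
    min_available_frac = min_available_frac,
    variability_sd = variability_sd,
    variability_rule = variability_rule,
    min_days_per_offset = as.integer(min_days_per_offset),
    ptb_normal = ptb_normal,
    ptd_normal = ptd_normal,
    ptb_bins = ptb_bins,
    minutes_slope = minutes_slope,
    updrs_per_level = updrs_per_level,
    updrs_at_target = updrs_at_target,
    calibration = calibration
  )
  structure(cfg, class = "fluct_config")
}

#' Read an analysis configuration from YAML
#'
#' Any key absent from the file keeps its [fluct_config()] default. The
#' calibration may be given as a `calibration:` mapping with `bks:` and
#' `level:` sequences.
#'
#' @param path Path to a YAML file.
#' @return A `"fluct_config"` list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$calibration)) {
    raw$calibration <- severity_calibration(
      bks = as.numeric(raw$calibration$bks),
      level = as.numeric(raw$calibration$level)
    )
  }
  known <- names(formals(fluct_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(fluct_config, raw)
}

#' @export
print.fluct_config <- function(x, ...) {
  cat("<fluct_config>\n")
  cat(sprintf("  daytime window : %s-%s (half-open)\n",
              format_clock(x$day_start), format_clock(x$day_end)))
  cat(sprintf("  sleep BKS >= %g; inactivity moving-median BKS > %g (%d epochs)\n",
              x$sleep_bks, x$inactivity_threshold, x$inactivity_window))
  cat(sprintf("  target level %g; response >= %g; wearing-off >= %g within %g min\n",
              x$target_level, x$response_threshold, x$wearing_off_threshold,
              x$wearing_off_horizon_min))
  cat(sprintf("  PTE window %g-%g min post-dose; PTB normal < %g%%; PTD normal < %g%%\n",
              x$pte_window_min[1], x$pte_window_min[2], x$ptb_normal, x$ptd_normal))
  invisible(x)
}

# "HH:MM" -> minutes since midnight
parse_clock <- function(x) {
  if (is.numeric(x)) return(x)
  m <- regmatches(x, regexec("^([0-2]?[0-9]):([0-5][0-9])$", x))[[1]]
  if (length(m) != 3L) stop("bad clock time: '", x, "'", call. = FALSE)
  as.numeric(m[2]) * 60 + as.numeric(m[3])
}

format_clock <- function(min_of_day) {
  sprintf("%02d:%02d", min_of_day %/% 60, round(min_of_day %% 60))
}
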