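# Epoch masks: which 2-minute epochs are "available" for each score.
#
# Scores pool epochs from the daytime window only, drop epochs where the
# logger was not worn, drop sleep (BKS >= 80) where stated, and for the
# "active" scores (active median BKS, PTB) also drop inactivity: sustained
# high scores whose 30-min moving median exceeds 40, where so few movements
# occur that bradykinesia cannot be assessed.

#' Centred moving median over the epoch grid
#'
#' Median of the values inside a centred window of `window_epochs` epoch
#' slots. Windows truncate at the edges of the recording; absent epochs
#' (gaps in the grid, or `NA` values) are skipped, never imputed, so the
#' median is taken over the values actually present in the window.
#'
#' @param x Numeric vector of per-epoch values.
#' @param window_epochs Odd integer window length in epoch slots (15 slots =
#'   30 min at 2-min epochs).
#' @param slots Optional integer epoch-slot index for each value (strictly
#'   increasing); supplies the grid when the recording has gaps. Defaults to
#'   `seq_along(x)` (contiguous recording).
#' @return Numeric vector, same length as `x`: the windowed median at each
#'   input position (`NA` where the window holds no present value).
#' @export
#' @examples
#' moving_median(c(10, 10, 10, 100, 10, 10, 10), 3)
moving_median <- function(x, window_epochs, slots = seq_along(x)) {
  if (length(window_epochs) != 1L || is.na(window_epochs) ||
      window_epochs < 3 || window_epochs %% 2 == 0) {
    stop("'window_epochs' must be an odd integer >= 3", call. = FALSE)
  }
  n <- length(x)
  if (n == 0L) return(numeric(0))
  if (length(slots) != n) stop("'slots' must match 'x' in length", call. = FALSE)
  if (n > 1L && any(diff(slots) <= 0)) {
    stop("'slots' must be strictly increasing", call. = FALSE)
  }
  half <- (window_epochs - 1L) / 2L
  out <- numeric(n)
  lo <- 1L
  hi <- 0L
  for (i in seq_len(n)) {
    # two-pointer sweep over the slot-based window
    while (lo <= n && slots[lo] < slots[i] - half) lo <- lo + 1L
    if (hi < i) hi <- i
    while (hi < n && slots[hi + 1L] <= slots[i] + half) hi <- hi + 1L
    out[i] <- median(x[lo:hi], na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out
}

#' Detect sleep epochs
#'
#' An epoch is flagged as sleep when its bradykinesia score is at or above
#' the sleep threshold (default 80), the level usually produced overnight.
#' Not-worn epochs are not flagged (they are excluded separately).
#'
#' @param recording A `pkg_recording`.
#' @param config A [fluct_config()].
#' @return Logical vector, one entry per epoch.
#' @export
detect_sleep <- function(recording, config = fluct_config()) {
  ep <- recording$epochs
  ep$worn & !is.na(ep$bks) & ep$bks >= config$sleep_bks
}

#' Detect inactivity epochs
#'
#' An epoch is inactive when the centred moving median (default 15 epochs =
#' 30 min) of the bradykinesia score is strictly greater than the inactivity
#' threshold (default 40). Only worn epochs contribute values to the median.
#'
#' @inheritParams detect_sleep
#' @return Logical vector, one entry per epoch.
#' @export
detect_inactivity <- function(recording, config = fluct_config()) {
  ep <- recording$epochs
  bks <- ifelse(ep$worn, ep$bks, NA_real_)
  mm <- moving_median(bks, config$inactivity_window, epoch_slots(ep$timestamp))
  !is.na(mm) & mm > config$inactivity_threshold
}

#' Daytime-window mask
#'
#' Epochs whose clock time falls in the half-open daytime window
#' `[day_start, day_end)`; with the default 09:00-18:00 window a fully
#' recorded day contributes exactly 270 two-minute epochs.
#'
#' @inheritParams detect_sleep
#' @return Logical vector, one entry per epoch.
#' @export
daytime_mask <- function(recording, config = fluct_config()) {
  m <- minute_of_day(recording$epochs$timestamp)
  m >= config$day_start & m < config$day_end
}

#' Availability masks for a recording
#'
#' Combines the per-epoch masks into the two availability notions used by
#' the scores: `available` (worn, daytime, not sleep) and `active_available`
#' (additionally not inactive), plus `fl_available` (worn and not sleep,
#' irrespective of the daytime window) used by the dose-response module.
#'
#' @inheritParams detect_sleep
#' @return Data frame with logical columns `worn`, `sleep`, `inactive`,
#'   `daytime`, `available`, `active_available`, `fl_available`, one row per
#'   epoch.
#' @export
epoch_masks <- function(recording, config = fluct_config()) {
  worn <- recording$epochs$worn
  sleep <- detect_sleep(recording, config)
  inactive <- detect_inactivity(recording, config)
  daytime <- daytime_mask(recording, config)
  available <- worn & daytime & !sleep
  data.frame(
    worn = worn,
    sleep = sleep,
    inactive = inactive,
    daytime = daytime,
    available = available,
    active_available = available & !inactive,
    fl_available = worn & !sleep
  )
}

# Integer 2-min epoch slot since the unix epoch; shared grid for all window
# arithmetic.
epoch_slots <- function(timestamps) {
  as.integer(floor(as.numeric(timestamps) / 120))
}

minute_of_day <- function(timestamps) {
  lt <- as.POSIXlt(timestamps, tz = "UTC")
  lt$hour * 60 + lt$min + lt$sec / 60
}

day_index <- function(timestamps) {
  as.integer(floor(as.numeric(timestamps) / 86400))
}
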