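# Fixtures are built in code; no data files.

# Epoch data frame on the regular 2-min grid starting at `start`.
make_epochs <- function(bks, dks = 0, start = "2024-03-04 09:00:00",
                        worn = TRUE, tremor = FALSE, walking = FALSE,
                        subject = "s1") {
  n <- length(bks)
  t0 <- as.POSIXct(start, tz = "UTC")
  data.frame(
    subject_id = subject,
    timestamp = t0 + 120 * (seq_len(n) - 1L),
    bks = bks,
    dks = rep_len(dks, n),
    worn = rep_len(worn, n),
    tremor = rep_len(tremor, n),
    walking = rep_len(walking, n)
  )
}

make_doses <- function(times, subject = "s1") {
  data.frame(subject_id = subject,
             reminder_time = as.POSIXct(times, tz = "UTC"),
             acknowledged = TRUE)
}

make_recording <- function(bks, ..., doses = NULL) {
  new_recording(make_epochs(bks, ...), doses)
}

# Multi-day recording whose bradykinesia score is a function of the minute
# of day, identical across days; used to construct known dose-response
# geometry without the simulator.
make_daily_recording <- function(bks_of_minute, days = 6,
                                 start_date = "2024-03-04",
                                 dose_clock = "07:00", subject = "s1") {
  t0 <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC")
  mins <- seq(0, 1438, by = 2)
  ts <- rep(t0 + 86400 * (seq_len(days) - 1L), each = length(mins)) +
    60 * rep(mins, days)
  mod <- rep(mins, days)
  ep <- data.frame(
    subject_id = subject, timestamp = ts,
    bks = bks_of_minute(mod), dks = 0,
    worn = TRUE, tremor = FALSE, walking = FALSE
  )
  doses <- if (!is.null(dose_clock)) {
    data.frame(
      subject_id = subject,
      reminder_time = rep(t0 + 86400 * (seq_len(days) - 1L), each = 1) +
        3600 * as.numeric(sub(":.*", "", dose_clock)) +
        60 * as.numeric(sub(".*:", "", dose_clock)),
      acknowledged = TRUE
    )
  } else {
    NULL
  }
  new_recording(ep, doses, subject)
}

# Brute-force oracle for the centred moving median on an epoch grid.
brute_moving_median <- function(x, window, slots = seq_along(x)) {
  half <- (window - 1) / 2
  vapply(seq_along(x), function(i) {
    sel <- abs(slots - slots[i]) <= half
    v <- x[sel]
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else median(v)
  }, numeric(1))
}

write_epoch_csv <- function(df, path = tempfile(fileext = ".csv")) {
  out <- df
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  path
}

write_dose_csv <- function(df, path = tempfile(fileext = ".csv")) {
  out <- df
  out$reminder_time <- format(out$reminder_time, "%Y-%m-%dT%H:%M:%S",
                              tz = "UTC")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  path
}
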