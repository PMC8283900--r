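# Reading and writing epoch files, dose-event files and subject summaries.
#
# Epoch CSV dialect: header subject_id,timestamp,bks,dks,worn,tremor,walking
# with ISO-8601 wall-clock timestamps. Missing epochs are represented by
# absence -- the reader never interpolates -- and every downstream denominator
# counts only epochs actually present.

EPOCH_COLUMNS <- c("subject_id", "timestamp", "bks", "dks",
                   "worn", "tremor", "walking")
DOSE_COLUMNS <- c("subject_id", "reminder_time", "acknowledged")

#' Read per-epoch scores from CSV
#'
#' Validates and sorts one record per 2-minute epoch. Timestamps must parse
#' as ISO-8601 wall-clock times (`YYYY-MM-DDTHH:MM:SS` or with a space);
#' booleans are accepted as 0/1/true/false, case-insensitive. Rows are
#' returned sorted by subject and timestamp; duplicate timestamps within a
#' subject and negative dyskinesia scores are errors that name the offending
#' data row.
#'
#' @param path Path to an epoch CSV file.
#' @return Data frame with columns `subject_id` (character), `timestamp`
#'   (POSIXct), `bks`, `dks` (numeric), `worn`, `tremor`, `walking`
#'   (logical).
#' @export
read_epochs <- function(path) {
  df <- read_table_checked(path, EPOCH_COLUMNS)
  if (nrow(df) == 0L) {
    return(data.frame(subject_id = character(), timestamp = empty_time(),
                      bks = numeric(), dks = numeric(), worn = logical(),
                      tremor = logical(), walking = logical()))
  }
  ts <- parse_timestamp(df$timestamp, path)
  out <- data.frame(
    subject_id = as.character(df$subject_id),
    timestamp = ts,
    bks = parse_numeric(df$bks, "bks", path),
    dks = parse_numeric(df$dks, "dks", path),
    worn = parse_bool(df$worn, "worn", path),
    tremor = parse_bool(df$tremor, "tremor", path),
    walking = parse_bool(df$walking, "walking", path)
  )
  bad <- which(!is.na(out$dks) & out$dks < 0)
  if (length(bad)) {
    stop(path, ": negative dks at data row ", bad[1], call. = FALSE)
  }
  out <- out[order(out$subject_id, out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  dup <- duplicated(out[c("subject_id", "timestamp")])
  if (any(dup)) {
    stop(path, ": duplicate timestamp ",
         format(out$timestamp[which(dup)[1]], "%Y-%m-%dT%H:%M:%S"),
         " for subject ", out$subject_id[which(dup)[1]], call. = FALSE)
  }
  out
}

#' Read dose-reminder events from CSV
#'
#' @param path Path to a dose CSV with header
#'   `subject_id,reminder_time,acknowledged`. An empty (header-only) file is
#'   valid and yields an empty collection; downstream, such subjects have no
#'   estimable first-dose window.
#' @return Data frame with `subject_id`, `reminder_time` (POSIXct),
#'   `acknowledged` (logical), sorted by subject and time.
#' @export
read_doses <- function(path) {
  df <- read_table_checked(path, DOSE_COLUMNS)
  if (nrow(df) == 0L) {
    return(data.frame(subject_id = character(), reminder_time = empty_time(),
                      acknowledged = logical()))
  }
  out <- data.frame(
    subject_id = as.character(df$subject_id),
    reminder_time = parse_timestamp(df$reminder_time, path),
    acknowledged = parse_bool(df$acknowledged, "acknowledged", path)
  )
  out <- out[order(out$subject_id, out$reminder_time), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble a subject recording
#'
#' @param epochs Epoch data frame as returned by [read_epochs()] (single
#'   subject; the `subject_id` column is dropped into the object).
#' @param doses Dose data frame as returned by [read_doses()], or `NULL`.
#' @param subject_id Subject identifier; defaults to the one in `epochs`.
#' @param ledd Levodopa-equivalent daily dose, mg/day (optional).
#' @param clinical Optional named list of clinical-scale scores.
#' @return An object of class `"pkg_recording"`.
#' @export
new_recording <- function(epochs, doses = NULL, subject_id = NULL,
                          ledd = NA_real_, clinical = list()) {
  if (is.null(subject_id)) {
    ids <- unique(epochs$subject_id)
    if (length(ids) != 1L) {
      stop("epochs contain ", length(ids),
           " subject ids; pass a single subject", call. = FALSE)
    }
    subject_id <- ids
  }
  ep <- epochs[epochs$subject_id == subject_id | is.null(epochs$subject_id), ,
               drop = FALSE]
  ep <- ep[order(ep$timestamp), setdiff(names(ep), "subject_id"), drop = FALSE]
  rownames(ep) <- NULL
  if (nrow(ep) == 0L) stop("no epochs for subject ", subject_id, call. = FALSE)
  span_days <- diff(range(as.numeric(ep$timestamp))) / 86400
  if (span_days > 10) {
    stop("recording spans ", round(span_days, 1),
         " days; at most 10 supported", call. = FALSE)
  }
  if (!is.null(doses) && "subject_id" %in% names(doses)) {
    doses <- doses[doses$subject_id == subject_id,
                   setdiff(names(doses), "subject_id"), drop = FALSE]
    rownames(doses) <- NULL
  }
  structure(
    list(subject_id = subject_id, epochs = ep,
         doses = doses %||% data.frame(reminder_time = empty_time(),
                                       acknowledged = logical()),
         ledd = ledd, clinical = clinical),
    class = "pkg_recording"
  )
}

#' Read a single-subject recording from epoch and dose files
#'
#' @param epoch_path,dose_path CSV paths; `dose_path` may be `NULL`.
#' @inheritParams new_recording
#' @return A `"pkg_recording"`.
#' @export
read_recording <- function(epoch_path, dose_path = NULL, subject_id = NULL,
                           ledd = NA_real_, clinical = list()) {
  epochs <- read_epochs(epoch_path)
  doses <- if (!is.null(dose_path)) read_doses(dose_path) else NULL
  new_recording(epochs, doses, subject_id, ledd, clinical)
}

#' @export
print.pkg_recording <- function(x, ...) {
  cat(sprintf("<pkg_recording> subject %s: %d epochs (%s to %s), %d dose reminders\n",
              x$subject_id, nrow(x$epochs),
              format(min(x$epochs$timestamp), "%Y-%m-%d %H:%M"),
              format(max(x$epochs$timestamp), "%Y-%m-%d %H:%M"),
              nrow(x$doses)))
  invisible(x)
}

#' Write (and read back) per-subject summary rows
#'
#' One row per subject with all summary scores and fluctuation-assessment
#' fields, written at full precision so a write-then-read round trip is
#' lossless. An empty cohort writes a header-only file.
#'
#' @param summaries Data frame of per-subject rows, as produced by
#'   [summarize_subject()] / `rbind`.
#' @param path Output path; `.json` writes JSON, anything else CSV.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summaries, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(summaries, path, dataframe = "rows", digits = NA,
                         na = "null", pretty = TRUE)
  } else {
    df <- summaries
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) {
      ifelse(is.na(v), NA, sprintf("%.17g", v))
    })
    write.csv(df, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' @rdname write_summary
#' @export
read_summary <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    out <- as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    out <- read.csv(path, stringsAsFactors = FALSE)
  }
  out
}

#' Write epochs / doses in the package CSV dialect
#'
#' @param recording A `pkg_recording`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(recording, path) {
  ep <- recording$epochs
  df <- data.frame(
    subject_id = recording$subject_id,
    timestamp = format(ep$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    bks = sprintf("%.17g", ep$bks),
    dks = sprintf("%.17g", ep$dks),
    worn = as.integer(ep$worn),
    tremor = as.integer(ep$tremor),
    walking = as.integer(ep$walking)
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_epochs
#' @export
write_doses <- function(recording, path) {
  d <- recording$doses
  df <- data.frame(
    subject_id = rep(recording$subject_id, nrow(d)),
    reminder_time = format(d$reminder_time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    acknowledged = as.integer(d$acknowledged)
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# -- parsing helpers ---------------------------------------------------------

read_table_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(path, ": missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}

parse_timestamp <- function(x, path) {
  clean <- sub("T", " ", x, fixed = TRUE)
  # element-wise so one malformed row cannot poison the others
  ts <- as.POSIXct(strptime(clean, "%Y-%m-%d %H:%M:%S", tz = "UTC"))
  miss <- is.na(ts)
  if (any(miss)) {
    ts[miss] <- as.POSIXct(strptime(clean[miss], "%Y-%m-%d %H:%M",
                                    tz = "UTC"))
  }
  if (anyNA(ts)) {
    row <- which(is.na(ts))[1]
    stop(path, ": malformed timestamp '", x[row], "' at data row ", row,
         call. = FALSE)
  }
  ts
}

parse_numeric <- function(x, field, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & nzchar(x))
  if (length(bad)) {
    stop(path, ": non-numeric ", field, " '", x[bad[1]], "' at data row ",
         bad[1], call. = FALSE)
  }
  out
}

parse_bool <- function(x, field, path) {
  low <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[low %in% c("1", "true", "t")] <- TRUE
  out[low %in% c("0", "false", "f")] <- FALSE
  bad <- which(is.na(out) & !is.na(x) & nzchar(x))
  if (length(bad)) {
    stop(path, ": bad boolean ", field, " '", x[bad[1]], "' at data row ",
         bad[1], call. = FALSE)
  }
  out
}

empty_time <- function() as.POSIXct(character(), tz = "UTC")

`%||%` <- function(a, b) if (is.null(a)) b else a
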