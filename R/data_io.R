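# Readers and writers for the per-subject two-column CSV pairs
# (Dexcom.csv: timestamp, glucose mg/dL at 5 min; TEMP.csv: timestamp,
# temperature degC at 4 Hz). Timestamps are timezone-naive local clock time;
# they are stored as POSIXct in UTC so that wall-clock hours are preserved.

TG_TZ <- "UTC"

# Accepted timestamp dialects: "YYYY-MM-DD HH:MM:SS(.fff)" and ISO-8601 with
# a "T" separator. Fractional seconds are required for the 4 Hz stream.
parse_tg_time <- function(x) {
  x <- trimws(x)
  out <- as.POSIXct(strptime(x, "%Y-%m-%d %H:%M:%OS", tz = TG_TZ))
  bad <- is.na(out) & nzchar(x)
  if (any(bad)) {
    out[bad] <- as.POSIXct(strptime(x[bad], "%Y-%m-%dT%H:%M:%OS", tz = TG_TZ))
  }
  out
}

new_trace <- function(time, value, value_name, subject_id, kind) {
  df <- structure(list(time, value),
                  names = c("time", value_name),
                  row.names = c(NA_integer_, -length(value)),
                  subject_id = subject_id,
                  class = c(kind, "tg_trace", "data.frame"))
  df
}

read_two_column_csv <- function(path, value_name, subject_id, kind, what) {
  if (!file.exists(path)) stop("cannot read ", what, " file: ", path)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  blank.lines.skip = TRUE)
  if (ncol(raw) < 2) stop(what, " file must have two columns: ", path)
  if (nrow(raw) == 0) {
    warning("empty data section in ", path)
    return(new_trace(as.POSIXct(character(), tz = TG_TZ), numeric(),
                     value_name, subject_id, kind))
  }
  ts <- parse_tg_time(raw[[1]])
  val <- suppressWarnings(as.numeric(raw[[2]]))
  # unparseable timestamps make the row unusable; unparseable/empty value
  # cells are kept as missing samples at that timestamp
  bad_ts <- is.na(ts)
  if (any(bad_ts)) {
    warning(sum(bad_ts), " row(s) with unparseable timestamp dropped in ", path)
    ts <- ts[!bad_ts]; val <- val[!bad_ts]
  }
  val[!is.finite(val)] <- NA_real_
  ord <- order(ts)
  ts <- ts[ord]; val <- val[ord]
  dup <- duplicated(as.numeric(ts))
  if (any(dup)) {
    warning(sum(dup), " duplicate timestamp(s) in ", path, "; first kept")
    ts <- ts[!dup]; val <- val[!dup]
  }
  new_trace(ts, val, value_name, subject_id, kind)
}

#' Read a CGM trace from a two-column CSV
#'
#' Expects a single header row, timestamps in the first column and glucose
#' (mg/dL) in the second, one sample nominally every 5 minutes. Rows are
#' sorted by time; duplicate timestamps keep the first occurrence; empty or
#' non-numeric glucose cells become missing values at their timestamp (they
#' are not dropped); rows whose timestamp cannot be parsed are counted and
#' dropped with a warning.
#'
#' @param path Path to the CSV file (`Dexcom.csv` layout).
#' @param subject_id Identifier attached to the trace; defaults to the name
#'   of the containing folder.
#' @return A `cgm_trace` data frame with columns `time` (POSIXct) and
#'   `glucose` (mg/dL).
#' @export
read_cgm_csv <- function(path, subject_id = basename(dirname(path))) {
  read_two_column_csv(path, "glucose", subject_id, "cgm_trace", "CGM")
}

#' Read a skin-temperature trace from a two-column CSV
#'
#' Expects a single header row, timestamps in the first column and skin
#' temperature (degrees Celsius) in the second, nominally at 4 Hz. No
#' screening happens here; sub-28 degree values are parsed as-is and
#' handled later by [screen_window()].
#'
#' @inheritParams read_cgm_csv
#' @return A `temp_trace` data frame with columns `time` (POSIXct) and
#'   `temperature` (degrees Celsius).
#' @export
read_temperature_csv <- function(path, subject_id = basename(dirname(path))) {
  read_two_column_csv(path, "temperature", subject_id, "temp_trace", "temperature")
}

#' Write a trace back to the two-column CSV dialect
#'
#' Inverse of the readers: re-reading the written file reproduces the
#' timestamps and values exactly (temperatures carry two decimals, the 4 Hz
#' timestamps two fractional-second digits, matching the deposit layout).
#'
#' @param trace A `cgm_trace` or `temp_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "tg_trace"))
  is_temp <- inherits(trace, "temp_trace")
  ts <- format(trace$time, if (is_temp) "%Y-%m-%d %H:%M:%OS2" else "%Y-%m-%d %H:%M:%S",
               tz = TG_TZ)
  val <- trace[[2]]
  vstr <- ifelse(is.na(val), "",
                 if (is_temp) sprintf("%.2f", val) else sprintf("%g", val))
  df <- data.frame(ts, vstr)
  names(df) <- c("Timestamp", names(trace)[2])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summarize CGM completeness for one subject
#'
#' The expected sample count is derived from the subject's own observed
#' monitoring span (`floor(span / cadence) + 1`), not from a nominal
#' protocol length, because spans differ per subject. Observed samples are
#' rows with a finite glucose value.
#'
#' @param cgm A `cgm_trace`.
#' @param cadence_s Nominal CGM cadence in seconds.
#' @return A list of class `tg_completeness` with fields `subject_id`,
#'   `expected_cgm_samples`, `observed_cgm_samples`, `percent_missing_cgm`
#'   and `monitoring_span_s`.
#' @export
#' @examples
#' tm <- as.POSIXct("2024-03-01", tz = "UTC") + 300 * (0:288)
#' cgm <- data.frame(time = tm, glucose = 100)
#' class(cgm) <- c("cgm_trace", "tg_trace", "data.frame")
#' summarize_completeness(cgm)$percent_missing_cgm   # 0
summarize_completeness <- function(cgm, cadence_s = 300) {
  stopifnot(inherits(cgm, "cgm_trace"))
  if (nrow(cgm) == 0) stop("empty CGM trace: subject unusable")
  span <- as.numeric(max(cgm$time)) - as.numeric(min(cgm$time))
  expected <- floor(span / cadence_s) + 1
  observed <- sum(is.finite(cgm$glucose))
  pct <- 100 * (1 - min(observed, expected) / expected)
  out <- list(subject_id = attr(cgm, "subject_id"),
              expected_cgm_samples = expected,
              observed_cgm_samples = observed,
              percent_missing_cgm = pct,
              monitoring_span_s = span)
  class(out) <- "tg_completeness"
  out
}

#' @export
print.tg_completeness <- function(x, ...) {
  cat(sprintf("Subject %s: %d/%d CGM samples observed (%.1f%% missing) over %.1f days\n",
              x$subject_id, x$observed_cgm_samples, x$expected_cgm_samples,
              x$percent_missing_cgm, x$monitoring_span_s / 86400))
  invisible(x)
}

#' Read the two traces of one subject folder
#'
#' @param dir Folder containing `Dexcom.csv` and `TEMP.csv`.
#' @return A list with elements `cgm` and `temp`.
#' @export
read_subject_dir <- function(dir) {
  list(cgm = read_cgm_csv(file.path(dir, "Dexcom.csv"), basename(dir)),
       temp = read_temperature_csv(file.path(dir, "TEMP.csv"), basename(dir)))
}
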