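# Subject exclusion, backward 5-min window alignment and window screening.
#
# Each CGM timestamp t defines one candidate window over the half-open
# interval (t - window_seconds, t]; a full window holds exactly
# window_seconds * temp_hz samples (1200 at the defaults). Half-open bounds
# prevent a sample from being counted in two adjacent windows. Screening
# verdict precedence: missing glucose < missing temperature < artifact <
# outlier; a window gets the first applicable verdict.

TG_VERDICTS <- c("retained",
                 "discarded_missing_glucose",
                 "discarded_missing_temperature",
                 "discarded_artifact",
                 "discarded_outlier")

#' Decide whether a subject is kept for analysis
#'
#' Subjects are excluded when their percentage of missing CGM samples is
#' strictly greater than the threshold (default 20%); a subject at exactly
#' the threshold is kept.
#'
#' @param summary A `tg_completeness` from [summarize_completeness()].
#' @param threshold_pct Exclusion threshold in percent, in (0, 100].
#' @return A list with `subject_id`, `percent_missing_cgm` and logical
#'   `exclude`.
#' @export
exclude_subject <- function(summary, threshold_pct = 20) {
  stopifnot(inherits(summary, "tg_completeness"),
            threshold_pct > 0, threshold_pct <= 100)
  list(subject_id = summary$subject_id,
       percent_missing_cgm = summary$percent_missing_cgm,
       exclude = summary$percent_missing_cgm > threshold_pct)
}

#' Align the temperature stream into backward windows
#'
#' Cuts one candidate window per CGM timestamp from the 4 Hz stream,
#' backward over `(t - window_seconds, t]`. Windows whose glucose value is
#' missing are marked `discarded_missing_glucose`; windows holding fewer
#' (or more) than the nominal `window_seconds * temp_hz` samples are marked
#' `discarded_missing_temperature`. No value screening happens here.
#'
#' @param temp A `temp_trace`.
#' @param cgm A `cgm_trace` of the same subject.
#' @param config A [tg_config()] list.
#' @return An object of class `tg_windows`: a list with `cgm_time`,
#'   `glucose`, `verdict` (one entry per CGM timestamp, chronological) and
#'   `samples`, a `samples_per_window` x n_candidate matrix whose columns
#'   are the full windows (column order follows `which(candidate)`).
#' @export
align_windows <- function(temp, cgm, config = tg_config()) {
  stopifnot(inherits(temp, "temp_trace"), inherits(cgm, "cgm_trace"))
  n_win <- nrow(cgm)
  N <- config$samples_per_window
  tt <- as.numeric(temp$time)
  ct <- as.numeric(cgm$time)
  hi <- findInterval(ct, tt)                        # last sample <= t
  lo <- findInterval(ct - config$window_seconds, tt) # last sample <= t - W (excluded)
  count <- hi - lo
  verdict <- rep("candidate", n_win)
  verdict[count != N] <- "discarded_missing_temperature"
  verdict[!is.finite(cgm$glucose)] <- "discarded_missing_glucose"
  cand <- verdict == "candidate"
  samples <- if (any(cand)) {
    .gather_windows_cpp(temp$temperature, as.integer(hi[cand]), N)
  } else {
    matrix(numeric(), nrow = N, ncol = 0)
  }
  if (anyNA(samples)) {
    # explicit missing markers inside a full-count window also count as
    # missing temperature data
    bad <- colSums(is.na(samples)) > 0
    verdict[which(cand)[bad]] <- "discarded_missing_temperature"
    samples <- samples[, !bad, drop = FALSE]
  }
  structure(list(subject_id = attr(cgm, "subject_id"),
                 cgm_time = cgm$time,
                 glucose = cgm$glucose,
                 verdict = verdict,
                 samples = samples),
            class = "tg_windows")
}

window_sd <- function(x, denominator) {
  n <- nrow(x)
  mu <- colMeans(x)
  ss <- colSums((x - rep(mu, each = n))^2)
  sqrt(ss / if (denominator == "sample") n - 1 else n)
}

#' Screen one full window for artifacts and outliers
#'
#' A window is discarded as artifact if any sample is strictly below the
#' artifact floor (28 degrees Celsius by default, chosen for free-living
#' wrist recordings); otherwise it is discarded as outlier if any sample
#' lies strictly outside the window-local mean +/- k*SD band (k = 5 by
#' default); otherwise it is retained. Equality at either bound retains
#' the sample; a constant window (SD = 0) is retained.
#'
#' @param samples Numeric vector of the window's temperature samples.
#' @param artifact_floor_c Artifact threshold, degrees Celsius.
#' @param outlier_k SD multiplier of the outlier band.
#' @param sd_denominator `"sample"` (n-1) or `"population"` (n).
#' @return One of `"retained"`, `"discarded_artifact"`,
#'   `"discarded_outlier"`.
#' @export
#' @examples
#' screen_window(rep(32, 1200))              # "retained"
#' screen_window(c(rep(32, 1199), 27.5))     # "discarded_artifact"
screen_window <- function(samples, artifact_floor_c = 28, outlier_k = 5,
                          sd_denominator = "sample") {
  stopifnot(all(is.finite(samples)))
  if (any(samples < artifact_floor_c)) return("discarded_artifact")
  mu <- mean(samples)
  s <- window_sd(matrix(samples, ncol = 1), sd_denominator)
  if (any(samples < mu - outlier_k * s | samples > mu + outlier_k * s)) {
    return("discarded_outlier")
  }
  "retained"
}

#' Screen every candidate window of an aligned set
#'
#' Vectorized [screen_window()] over a `tg_windows` object; candidate
#' windows receive their final verdict and discarded columns are dropped
#' from the sample matrix.
#'
#' @param w A `tg_windows` from [align_windows()].
#' @param config A [tg_config()] list.
#' @return The updated `tg_windows`.
#' @export
screen_windows <- function(w, config = tg_config()) {
  cand <- w$verdict == "candidate"
  if (!any(cand)) return(w)
  x <- w$samples
  n <- nrow(x)
  st <- .window_stats_cpp(x, 36, 32)
  artifact <- st$min < config$artifact_floor_c
  denom <- if (config$sd_denominator == "sample") max(n - 1, 1) else n
  s <- sqrt(st$ss / denom)
  outlier <- !artifact & st$max_absdev > config$outlier_sd_multiplier * s
  v <- rep("retained", ncol(x))
  v[artifact] <- "discarded_artifact"
  v[outlier] <- "discarded_outlier"
  w$verdict[cand] <- v
  keep <- v == "retained"
  w$samples <- x[, keep, drop = FALSE]
  w
}

#' Preprocess one subject: align, screen, report
#'
#' Runs [align_windows()] then screens every candidate window, producing
#' the retained window set (re-indexed chronologically, ready for the
#' retrospective metrics) and a conservation report.
#'
#' @inheritParams align_windows
#' @return A list with `windows` (a screened `tg_windows` whose `samples`
#'   columns are the retained windows) and `report` (class `tg_report`).
#' @export
preprocess_subject <- function(temp, cgm, config = tg_config()) {
  w <- screen_windows(align_windows(temp, cgm, config), config)
  counts <- vapply(TG_VERDICTS, function(v) sum(w$verdict == v), integer(1))
  report <- structure(list(subject_id = w$subject_id,
                           windows_total = length(w$verdict),
                           windows_retained = counts[["retained"]],
                           discard_counts = counts[TG_VERDICTS[-1]],
                           percent_retained =
                             if (length(w$verdict))
                               100 * counts[["retained"]] / length(w$verdict)
                             else NA_real_),
                      class = "tg_report")
  list(windows = w, report = report)
}

#' @export
print.tg_report <- function(x, ...) {
  cat(sprintf("Subject %s: %d windows, %d retained (%.1f%%)\n",
              x$subject_id, x$windows_total, x$windows_retained,
              x$percent_retained))
  d <- x$discard_counts
  for (nm in names(d)) if (d[[nm]] > 0) cat(sprintf("  %s: %d\n", nm, d[[nm]]))
  invisible(x)
}

#' Extract the retained windows of a screened set
#'
#' @param w A screened `tg_windows`.
#' @return A list with `subject_id`, `cgm_time`, `glucose` and the
#'   `samples` matrix restricted to retained windows.
#' @export
retained_windows <- function(w) {
  keep <- w$verdict == "retained"
  list(subject_id = w$subject_id,
       cgm_time = w$cgm_time[keep],
       glucose = w$glucose[keep],
       samples = w$samples)
}
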