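# Glycemic-range and day/night labelling of retained windows.

#' Classify glucose values against the tight range
#'
#' Below range (BR) strictly under the lower bound, above range (AR)
#' strictly over the upper bound, in range (IR) otherwise — both bounds
#' (70 and 140 mg/dL by default) belong to IR.
#'
#' @param glucose Numeric vector of glucose values, mg/dL; must be positive.
#' @param tight_range_mg_dl Length-2 inclusive IR bounds.
#' @return Factor with levels `IR`, `AR`, `BR`.
#' @export
#' @examples
#' classify_glycemia(c(69, 70, 105, 140, 141))
classify_glycemia <- function(glucose, tight_range_mg_dl = c(70, 140)) {
  if (any(!is.finite(glucose) | glucose <= 0)) {
    stop("glucose values must be positive and finite")
  }
  lab <- rep("IR", length(glucose))
  lab[glucose < tight_range_mg_dl[1]] <- "BR"
  lab[glucose > tight_range_mg_dl[2]] <- "AR"
  factor(lab, levels = c("IR", "AR", "BR"))
}

#' Classify timestamps into daytime and nighttime
#'
#' Daytime is the half-open wall-clock interval [06:00, 21:00) by default;
#' each boundary instant belongs to the period it opens (06:00:00 is
#' daytime, 21:00:00 is nighttime).
#'
#' @param time POSIXct vector carrying wall-clock time.
#' @param daytime_hours Length-2 numeric daytime bounds in hours.
#' @return Factor with levels `daytime`, `nighttime`.
#' @export
#' @examples
#' tz <- "UTC"
#' classify_period(as.POSIXct(c("2024-03-01 05:59:59", "2024-03-01 06:00:00",
#'                              "2024-03-01 21:00:00"), tz = tz))
classify_period <- function(time, daytime_hours = c(6, 21)) {
  lt <- as.POSIXlt(time, tz = TG_TZ)
  h <- lt$hour + lt$min / 60 + lt$sec / 3600
  day <- h >= daytime_hours[1] & h < daytime_hours[2]
  factor(ifelse(day, "daytime", "nighttime"), levels = c("daytime", "nighttime"))
}

#' Attach glycemic-range and period labels to a metric series
#'
#' @param series A `tg_series` from [compute_metric_series()].
#' @param config A [tg_config()] list.
#' @return The series with added factor columns `range` and `period`, class
#'   `tg_labeled`; attribute `cell_counts` holds the range x period table.
#' @export
stratify <- function(series, config = tg_config()) {
  out <- series
  out$range <- classify_glycemia(series$glucose, config$tight_range_mg_dl)
  out$period <- classify_period(series$time, config$daytime_hours)
  attr(out, "cell_counts") <- table(out$range, out$period)
  class(out) <- c("tg_labeled", "data.frame")
  attr(out, "subject_id") <- attr(series, "subject_id")
  out
}
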