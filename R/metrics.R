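# Current-window and retrospective skin-temperature variability metrics.
#
# Current metrics, per window i with samples st_i1..st_iN:
#   mean_T, median_T, SD_T, IQR_T, CV_T = SD_T/mean_T,
#   MAD_T = 1.4826 * sum(|st_ik - median_T|) / N      (mean amplitude
#     deviation; 1.4826 ensures asymptotically normal consistency),
#   J_T   = 0.001 * (mean_T + SD_T)^2                 (J-index adaptation),
#   M1_T, M2_T = sum(|10*log10(st_ik / r)|^3) / N     (M-value adaptation,
#     r = 36 degC for M1, 32 degC for M2).
# Retrospective metrics, over retained windows 1..i:
#   CV_T_mean = sum(CV_Tk) / i
#   CV_T_SD   = sqrt(sum((CV_Tk - CV_T_mean)^2) / i)   (population form)
#   SD_T_hhmm = sqrt(sum((mean_Tk - m)^2) / i), m the grand mean of all
#     samples so far (equal-length windows make m the mean of window means).

TG_METRICS <- c("mean_T", "median_T", "SD_T", "IQR_T", "CV_T", "MAD_T",
                "J_T", "M1_T", "M2_T", "CV_T_mean", "CV_T_SD", "SD_T_hhmm")

# data.frame() without its per-column coercion overhead (hot path)
fast_df <- function(cols) {
  structure(cols, row.names = c(NA_integer_, -length(cols[[1]])),
            class = "data.frame")
}


#' Current-behavior metrics of one or more windows
#'
#' Computes the nine within-window metrics. Quartiles use linear
#' interpolation between order statistics (R's default type 7); SD uses the
#' sample (n-1) denominator unless configured otherwise.
#'
#' @param samples Numeric vector (one window) or matrix with one window per
#'   column; all values must be finite and positive.
#' @param r1,r2 Reference temperatures (degrees Celsius) of the two M-value
#'   adaptations.
#' @param m_value_form,sd_denominator See [tg_config()].
#' @return A data frame with one row per window and columns `mean_T`,
#'   `median_T`, `SD_T`, `IQR_T`, `CV_T`, `MAD_T`, `J_T`, `M1_T`, `M2_T`.
#' @export
#' @examples
#' current_metrics(rep(32, 1200))$J_T   # 0.001 * 32^2 = 1.024
current_metrics <- function(samples, r1 = 36, r2 = 32,
                            m_value_form = "cubed_abs",
                            sd_denominator = "sample") {
  x <- if (is.matrix(samples)) samples else matrix(samples, ncol = 1)
  if (!all(is.finite(x))) stop("non-finite sample in window (screening should have removed it)")
  n <- nrow(x)
  st <- .window_stats_cpp(x, r1, r2)
  if (any(st$mean <= 0)) stop("non-positive window mean")
  sdv <- sqrt(st$ss / if (sd_denominator == "sample") max(n - 1, 1) else n)
  fast_df(list(mean_T = st$mean,
               median_T = st$median,
               SD_T = sdv,
               IQR_T = st$q75 - st$q25,
               CV_T = sdv / st$mean,
               MAD_T = 1.4826 * st$mad_sum / n,
               J_T = 0.001 * (st$mean + sdv)^2,
               M1_T = if (m_value_form == "cubed_abs") st$m1_cube / n
                      else 3 * st$m1_sum / n,
               M2_T = if (m_value_form == "cubed_abs") st$m2_cube / n
                      else 3 * st$m2_sum / n))
}

#' Retrospective coefficient-of-variation metrics
#'
#' Running mean and running population SD (denominator i, exactly as
#' defined) of the per-window CV values of windows 1..i.
#'
#' @param cv_history Chronological numeric vector of CV_T values up to and
#'   including the current window.
#' @return A list with `CV_T_mean` and `CV_T_SD`.
#' @export
retrospective_cv <- function(cv_history) {
  if (length(cv_history) == 0) stop("empty CV history")
  m <- mean(cv_history)
  list(CV_T_mean = m,
       CV_T_SD = sqrt(mean((cv_history - m)^2)))
}

#' Retrospective SD of the window-mean series
#'
#' Population SD (denominator i) of the window means of windows 1..i about
#' the grand mean m of all temperature samples so far. With equal-length
#' windows m coincides with the mean of the window means, which is the
#' default when `m` is not supplied.
#'
#' @param window_means Chronological numeric vector of per-window means.
#' @param m Grand mean of all samples across windows 1..i; defaults to
#'   `mean(window_means)`.
#' @return The running SD, a scalar (0 at i = 1).
#' @export
sd_hhmm <- function(window_means, m = mean(window_means)) {
  if (length(window_means) == 0) stop("empty window-mean history")
  sqrt(mean((window_means - m)^2))
}

# Running population mean/SD of a vector at every prefix, computed with a
# centered cumulative-sum recurrence so the streaming values agree with
# batch recomputation to tight tolerance.
running_pop_stats <- function(x) {
  i <- seq_along(x)
  c0 <- x[1]
  xc <- x - c0
  m <- cumsum(xc) / i
  v <- cumsum(xc^2) / i - m^2
  list(mean = m + c0, sd = sqrt(pmax(v, 0)))
}

#' Compute the full metric series of one subject
#'
#' Current metrics for every retained window plus the retrospective metrics
#' accumulated over retained windows only, chronologically, spanning the
#' whole recording (day and night interleaved). With `reset_daily = TRUE`
#' in the configuration, the retrospective accumulators restart at each
#' calendar-day boundary.
#'
#' @param retained Output of [preprocess_subject()] (the full list or its
#'   `windows` element).
#' @param config A [tg_config()] list.
#' @return A data frame of class `tg_series` with columns `index_i`, `time`,
#'   `glucose` and the 12 metrics; attribute `subject_id`.
#' @export
compute_metric_series <- function(retained, config = tg_config()) {
  if (!is.null(retained$windows)) retained <- retained$windows
  if (inherits(retained, "tg_windows")) retained <- retained_windows(retained)
  ord <- order(as.numeric(retained$cgm_time))
  tm <- retained$cgm_time[ord]
  glu <- retained$glucose[ord]
  x <- retained$samples[, ord, drop = FALSE]
  k <- ncol(x)
  cur <- if (k) current_metrics(x, config$m_refs_c[1], config$m_refs_c[2],
                                config$m_value_form, config$sd_denominator)
         else as.data.frame(setNames(rep(list(numeric()), 9), TG_METRICS[1:9]))
  retro <- fast_df(list(CV_T_mean = numeric(k), CV_T_SD = numeric(k),
                        SD_T_hhmm = numeric(k)))
  if (k) {
    groups <- if (config$reset_daily) format(tm, "%Y-%m-%d", tz = TG_TZ)
              else rep("all", k)
    for (g in unique(groups)) {
      sel <- groups == g
      cvs <- running_pop_stats(cur$CV_T[sel])
      mns <- running_pop_stats(cur$mean_T[sel])
      retro$CV_T_mean[sel] <- cvs$mean
      retro$CV_T_SD[sel] <- cvs$sd
      retro$SD_T_hhmm[sel] <- mns$sd
    }
  }
  out <- fast_df(c(list(index_i = seq_len(k), time = tm, glucose = glu),
                   as.list(cur), as.list(retro)))
  attr(out, "subject_id") <- retained$subject_id
  class(out) <- c("tg_series", "data.frame")
  out
}

#' @export
print.tg_series <- function(x, ...) {
  cat(sprintf("Metric series for subject %s: %d retained windows\n",
              attr(x, "subject_id"), nrow(x)))
  NextMethod()
}
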