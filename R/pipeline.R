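# End-to-end orchestration: subject exclusion, preprocessing, metrics,
# stratification, per-subject and cohort statistics, publication-shaped outputs.

hist_breaks <- function(lo, hi, width = 0.25) {
  seq(floor(lo / width) * width, ceiling(hi / width) * width, by = width)
}

#' Run the full analysis pipeline
#'
#' Accepts either a directory of per-subject folders (each holding
#' `Dexcom.csv` and `TEMP.csv`) or an in-memory list of subjects as
#' produced by [generate_cohort()]. Applies the completeness-based subject
#' exclusion, preprocesses and screens every kept subject, computes the
#' metric series, stratifies by glycemic range and period, runs the
#' per-subject Wilcoxon comparisons with FDR correction, fits the cohort
#' mixed-effects models, and assembles the significance summary plus the
#' before/after temperature histogram (0.25 degC bins).
#'
#' @param input Directory path, or a list of subjects (each a list with
#'   `cgm` and `temp` traces).
#' @param config A [tg_config()] list.
#' @param output_dir Optional directory; when given, tidy CSVs of every
#'   result table are written there.
#' @param fit_lme Set to FALSE to skip the cohort mixed-effects stage.
#' @param keep_series Keep the per-subject labeled metric series in the
#'   returned object.
#' @param histogram Accumulate the before/after temperature histogram
#'   (skippable for large simulation studies).
#' @param verbose Log progress and discard tallies to stderr.
#' @return An object of class `tg_cohort`; see [print.tg_cohort()].
#' @export
run_pipeline <- function(input, config = tg_config(), output_dir = NULL,
                         fit_lme = TRUE, keep_series = TRUE,
                         histogram = TRUE, verbose = FALSE) {
  log_msg <- function(...) if (verbose) message(sprintf(...))
  if (is.character(input)) {
    dirs <- list.dirs(input, recursive = FALSE)
    dirs <- dirs[file.exists(file.path(dirs, "Dexcom.csv"))]
    if (length(dirs) == 0) stop("no subject folders with Dexcom.csv under ", input)
    subjects <- lapply(dirs, read_subject_dir)
    names(subjects) <- basename(dirs)
  } else {
    subjects <- input
    if (length(subjects) == 0) stop("no subjects supplied")
    if (is.null(names(subjects))) {
      names(subjects) <- vapply(subjects, function(s) attr(s$cgm, "subject_id"), "")
    }
  }

  exclusions <- do.call(rbind, lapply(names(subjects), function(id) {
    cs <- summarize_completeness(subjects[[id]]$cgm, config$window_seconds)
    dec <- exclude_subject(cs, config$cgm_missing_exclusion_pct)
    data.frame(subject_id = id,
               expected_cgm = cs$expected_cgm_samples,
               observed_cgm = cs$observed_cgm_samples,
               percent_missing_cgm = cs$percent_missing_cgm,
               excluded = dec$exclude)
  }))
  kept <- exclusions$subject_id[!exclusions$excluded]
  if (length(kept) == 0) stop("no usable subjects after the completeness exclusion")
  log_msg("subjects kept: %d of %d", length(kept), nrow(exclusions))

  reports <- list(); labeled <- list()
  width <- 0.25
  breaks <- NULL; before_counts <- after_counts <- NULL
  if (histogram) {
    raw_ranges <- vapply(kept, function(id) {
      range(subjects[[id]]$temp$temperature, na.rm = TRUE)
    }, numeric(2))
    breaks <- hist_breaks(min(raw_ranges) - width, max(raw_ranges) + width, width)
    before_counts <- after_counts <- numeric(length(breaks) - 1)
  }

  for (id in kept) {
    s <- subjects[[id]]
    attr(s$cgm, "subject_id") <- id
    attr(s$temp, "subject_id") <- id
    pp <- preprocess_subject(s$temp, s$cgm, config)
    reports[[id]] <- pp$report
    log_msg("%s: %d/%d windows retained", id,
            pp$report$windows_retained, pp$report$windows_total)
    series <- compute_metric_series(pp$windows, config)
    labeled[[id]] <- stratify(series, config)
    if (histogram) {
      before_counts <- before_counts +
        hist(s$temp$temperature[is.finite(s$temp$temperature)],
             breaks = breaks, plot = FALSE)$counts
      if (ncol(pp$windows$samples)) {
        after_counts <- after_counts +
          hist(as.vector(pp$windows$samples), breaks = breaks, plot = FALSE)$counts
      }
    }
  }

  comparisons <- do.call(rbind, lapply(labeled, compare_subject, config = config))
  rownames(comparisons) <- NULL
  class(comparisons) <- c("tg_comparisons", "data.frame")
  models <- if (fit_lme) cohort_models(labeled, config) else NULL
  significance <- summarize_significance(comparisons)

  report_df <- do.call(rbind, lapply(reports, function(r) {
    data.frame(subject_id = r$subject_id, windows_total = r$windows_total,
               windows_retained = r$windows_retained,
               t(r$discard_counts), percent_retained = r$percent_retained)
  }))
  rownames(report_df) <- NULL

  out <- structure(list(exclusions = exclusions,
                        reports = report_df,
                        comparisons = comparisons,
                        cohort_models = models,
                        significance = significance,
                        histogram = if (histogram)
                          list(breaks = breaks, before = before_counts,
                               after = after_counts, width = width,
                               floor = config$artifact_floor_c),
                        series = if (keep_series) labeled else NULL,
                        config = config),
                   class = "tg_cohort")
  if (!is.null(output_dir)) export_cohort(out, output_dir)
  out
}

#' Write every tidy result table of a run to CSV
#'
#' @param cohort A `tg_cohort` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort$exclusions, file.path(dir, "exclusions.csv"), row.names = FALSE)
  write.csv(cohort$reports, file.path(dir, "preprocess_report.csv"), row.names = FALSE)
  write.csv(cohort$comparisons, file.path(dir, "comparisons.csv"), row.names = FALSE)
  if (!is.null(cohort$cohort_models)) {
    write.csv(cohort$cohort_models, file.path(dir, "cohort_models.csv"),
              row.names = FALSE)
  }
  write.csv(cohort$significance, file.path(dir, "significance_summary.csv"),
            row.names = FALSE)
  if (!is.null(cohort$series)) {
    series <- do.call(rbind, lapply(cohort$series, function(l) {
      cbind(subject_id = attr(l, "subject_id"), as.data.frame(l))
    }))
    write.csv(series, file.path(dir, "metric_series.csv"), row.names = FALSE)
  }
  hb <- cohort$histogram
  if (!is.null(hb)) {
    write.csv(data.frame(bin_lo = head(hb$breaks, -1), bin_hi = hb$breaks[-1],
                         before = hb$before, after = hb$after),
              file.path(dir, "temperature_histogram.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' @export
print.tg_cohort <- function(x, ...) {
  cat("Skin-temperature / glycemia analysis\n")
  cat(sprintf("  Subjects: %d analyzed, %d excluded (> %.0f%% missing CGM)\n",
              sum(!x$exclusions$excluded), sum(x$exclusions$excluded),
              x$config$cgm_missing_exclusion_pct))
  cat(sprintf("  Windows: %d total, %d retained (%.1f%%)\n",
              sum(x$reports$windows_total), sum(x$reports$windows_retained),
              100 * sum(x$reports$windows_retained) / sum(x$reports$windows_total)))
  top <- x$significance[!is.na(x$significance$pct_significant), , drop = FALSE]
  if (nrow(top)) {
    top <- top[order(-top$pct_significant), , drop = FALSE]
    cat("  Top metric cells by % of subjects significant (FDR < 0.05):\n")
    for (i in head(seq_len(nrow(top)), 4)) {
      cat(sprintf("    %-10s %-9s %-9s %5.1f%% (%d/%d)\n",
                  top$metric[i], top$contrast[i], top$period[i],
                  top$pct_significant[i], top$n_significant[i],
                  top$n_eligible[i]))
    }
  }
  invisible(x)
}

#' @export
summary.tg_cohort <- function(object, ...) {
  print(object)
  cat("\nPer-subject retention:\n")
  print(object$reports, row.names = FALSE)
  if (!is.null(object$cohort_models)) {
    cat("\nCohort mixed-effects models (FDR-corrected):\n")
    m <- object$cohort_models
    print(m[!is.na(m$p_fdr), c("metric", "contrast", "period", "estimate", "p_fdr")],
          row.names = FALSE, digits = 3)
  }
  invisible(object)
}

#' Histogram of temperature values before and after preprocessing
#'
#' 0.25 degC bins with the artifact floor marked.
#'
#' @param x A `tg_cohort`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.tg_cohort <- function(x, ...) {
  hb <- x$histogram
  mids <- head(hb$breaks, -1) + hb$width / 2
  plot(mids, hb$before, type = "s", col = "steelblue", xlab = "Skin temperature (°C)",
       ylab = "Samples per bin", main = "Before vs after preprocessing", ...)
  lines(mids, hb$after, type = "s", col = "darkorange")
  abline(v = hb$floor, col = "red", lty = 2)
  legend("topleft", legend = c("before", "after", "artifact floor"),
         col = c("steelblue", "darkorange", "red"), lty = c(1, 1, 2), bty = "n")
  invisible(x)
}

#' Render a per-subject table for one metric
#'
#' Rows are subjects; columns are range x period cells formatted as
#' `median[p25; p75]`, with significance flags in separate columns and "-"
#' for subjects without windows at that glycemic level. `M2_T` values are
#' rendered multiplied by 100 (the header notes the 10^-2 scale); stored
#' values are never scaled.
#'
#' @param cohort A `tg_cohort` (or row-bound [compare_subject()] output).
#' @param metric One of the 12 metric names.
#' @param digits Significant digits in the cells.
#' @return A character data frame; attribute `scale_note` records any
#'   rendering scale.
#' @export
render_subject_table <- function(cohort, metric, digits = 3) {
  stopifnot(metric %in% TG_METRICS)
  cmp <- if (inherits(cohort, "tg_cohort")) cohort$comparisons else cohort
  cmp <- cmp[cmp$metric == metric, , drop = FALSE]
  scale <- if (metric == "M2_T") 100 else 1
  fmt <- function(med, q25, q75, n) {
    ifelse(n == 0 | is.na(med), "-",
           sprintf("%.*g[%.*g; %.*g]", digits, med * scale,
                   digits, q25 * scale, digits, q75 * scale))
  }
  cols <- c("subject_id", "IR_day", "AR_day", "AR_day_sig", "BR_day",
            "BR_day_sig", "IR_night", "AR_night", "AR_night_sig",
            "BR_night", "BR_night_sig")
  subjects <- unique(cmp$subject_id)
  if (length(subjects) == 0) {
    out <- as.data.frame(setNames(rep(list(character()), length(cols)), cols))
    attr(out, "scale_note") <- NULL
    return(out)
  }
  rows <- lapply(subjects, function(sid) {
    d <- cmp[cmp$subject_id == sid, , drop = FALSE]
    cell <- function(ctr, per, what) {
      r <- d[d$contrast == ctr & d$period == per, , drop = FALSE]
      if (nrow(r) == 0) return("-")
      switch(what,
             ir = fmt(r$ref_median, r$ref_q25, r$ref_q75, r$n_ref),
             alt = fmt(r$alt_median, r$alt_q25, r$alt_q75, r$n_alt),
             sig = if (is.na(r$p_fdr)) "" else r$tier)
    }
    data.frame(subject_id = sid,
               IR_day = cell("AR-vs-IR", "daytime", "ir"),
               AR_day = cell("AR-vs-IR", "daytime", "alt"),
               AR_day_sig = cell("AR-vs-IR", "daytime", "sig"),
               BR_day = cell("BR-vs-IR", "daytime", "alt"),
               BR_day_sig = cell("BR-vs-IR", "daytime", "sig"),
               IR_night = cell("AR-vs-IR", "nighttime", "ir"),
               AR_night = cell("AR-vs-IR", "nighttime", "alt"),
               AR_night_sig = cell("AR-vs-IR", "nighttime", "sig"),
               BR_night = cell("BR-vs-IR", "nighttime", "alt"),
               BR_night_sig = cell("BR-vs-IR", "nighttime", "sig"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "scale_note") <- if (scale != 1)
    sprintf("%s values shown × 10^-%d", metric, round(log10(scale))) else NULL
  out
}
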