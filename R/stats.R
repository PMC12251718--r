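# Per-subject nonparametric comparisons (Wilcoxon rank-sum + BH-FDR),
# normality screening (Lilliefors), and cohort-level linear mixed-effects
# models with a per-subject random intercept.

#' Lilliefors normality test
#'
#' Kolmogorov-Smirnov test against a normal distribution with estimated
#' mean and variance. Used to screen metric distributions; the subject-level
#' comparisons are nonparametric regardless.
#'
#' @param values Numeric vector; at least 5 finite values with nonzero
#'   spread are required, otherwise the result is absent (`NA`).
#' @return The p-value, or `NA_real_` when the test is not applicable.
#' @export
lilliefors_test <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 5 || sd(values) == 0) return(NA_real_)
  nortest::lillie.test(values)$p.value
}

#' Two-sided Wilcoxon rank-sum comparison of one metric
#'
#' Compares the metric values of an AR or BR group against the IR reference
#' group. The exact null distribution is used for small untied samples
#' (n + m <= 25); otherwise the normal approximation with midranks and tie
#' correction. Groups below the minimum size yield an absent result,
#' mirroring "-" cells for subjects without the contrast.
#'
#' @param ref Numeric vector, IR metric values.
#' @param alt Numeric vector, AR or BR metric values.
#' @param min_group_size Smallest group size at which the test is run.
#' @param exact_max Largest n + m for which the exact distribution is used
#'   (when there are no ties).
#' @return `NULL` when a group is too small; otherwise a list with `p_raw`,
#'   `n_ref`, `n_alt` and `median`/`q25`/`q75` per group.
#' @export
wilcoxon_compare <- function(ref, alt, min_group_size = 4, exact_max = 25) {
  ref <- ref[is.finite(ref)]
  alt <- alt[is.finite(alt)]
  n <- length(ref); m <- length(alt)
  if (n < min_group_size || m < min_group_size) return(NULL)
  use_exact <- (n + m) <= exact_max && !anyDuplicated(c(ref, alt))
  p <- wilcox.test(alt, ref, exact = use_exact, correct = !use_exact)$p.value
  qs_r <- quantile(ref, c(0.25, 0.5, 0.75), names = FALSE)
  qs_a <- quantile(alt, c(0.25, 0.5, 0.75), names = FALSE)
  list(p_raw = p, n_ref = n, n_alt = m,
       ref_median = qs_r[2], ref_q25 = qs_r[1], ref_q75 = qs_r[3],
       alt_median = qs_a[2], alt_q25 = qs_a[1], alt_q75 = qs_a[3])
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjusted p-values: monotone, capped at 1, never below
#' the raw values. `NA` entries are preserved and excluded from the family.
#'
#' @param p_values Numeric vector of raw p-values in [0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  p.adjust(p_values, method = "BH")
}

significance_tier <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.01, "strong", ifelse(p < 0.05, "moderate", "none")))
}

#' Per-subject range comparisons for every metric
#'
#' Runs [wilcoxon_compare()] for each metric x contrast (AR vs IR, BR vs
#' IR) x period (daytime/nighttime) cell of one subject's labeled series,
#' then applies BH-FDR at the configured scope (default: across the metric
#' family within each subject x contrast x period cell). Cells whose groups
#' are below the minimum size are reported with `eligible` information but
#' no fabricated p-value.
#'
#' @param labeled A `tg_labeled` series from [stratify()].
#' @param config A [tg_config()] list.
#' @return A data frame of class `tg_comparisons`, one row per metric x
#'   contrast x period with columns `subject_id`, `metric`, `contrast`,
#'   `period`, `n_ref`, `n_alt`, group summaries, `p_raw`, `p_fdr`, `tier`.
#' @export
compare_subject <- function(labeled, config = tg_config()) {
  sid <- attr(labeled, "subject_id")
  n_cells <- 2L * 2L * length(TG_METRICS)
  out <- data.frame(subject_id = rep(sid, n_cells), metric = "", contrast = "",
                    period = "", n_ref = 0L, n_alt = 0L,
                    ref_median = NA_real_, ref_q25 = NA_real_, ref_q75 = NA_real_,
                    alt_median = NA_real_, alt_q25 = NA_real_, alt_q75 = NA_real_,
                    p_raw = NA_real_)
  i <- 0L
  per_f <- labeled$period
  ran_f <- labeled$range
  for (per in levels(per_f)) {
    in_per <- per_f == per
    ref_idx <- in_per & ran_f == "IR"
    for (ctr in c("AR", "BR")) {
      alt_idx <- in_per & ran_f == ctr
      for (metric in TG_METRICS) {
        i <- i + 1L
        res <- wilcoxon_compare(labeled[[metric]][ref_idx],
                                labeled[[metric]][alt_idx],
                                config$min_group_size)
        out$metric[i] <- metric
        out$contrast[i] <- paste0(ctr, "-vs-IR")
        out$period[i] <- per
        out$n_ref[i] <- sum(ref_idx)
        out$n_alt[i] <- sum(alt_idx)
        if (!is.null(res)) {
          out$ref_median[i] <- res$ref_median
          out$ref_q25[i] <- res$ref_q25
          out$ref_q75[i] <- res$ref_q75
          out$alt_median[i] <- res$alt_median
          out$alt_q25[i] <- res$alt_q25
          out$alt_q75[i] <- res$alt_q75
          out$p_raw[i] <- res$p_raw
        }
      }
    }
  }
  scope <- if (config$fdr_scope == "per_cell") {
    interaction(out$contrast, out$period, drop = TRUE)
  } else {
    factor(out$contrast)
  }
  out$p_fdr <- NA_real_
  for (g in levels(scope)) {
    sel <- scope == g
    out$p_fdr[sel] <- bh_fdr(out$p_raw[sel])
  }
  out$tier <- significance_tier(out$p_fdr)
  class(out) <- c("tg_comparisons", "data.frame")
  out
}

#' Cohort-level linear mixed-effects model for one metric
#'
#' Fits `value ~ glycemic_level + (1 | subject)` by maximum likelihood on
#' (by default) square-root-transformed metric values, with IR as the
#' reference level, separately per contrast. The fixed-effect p-value uses
#' the Satterthwaite approximation.
#'
#' @param data Data frame with columns `subject_id`, `value`, `range`
#'   (factor with IR plus the alternative level) for one metric, contrast
#'   and period across subjects.
#' @param sqrt_transform Apply the square-root transform before fitting.
#' @param p_method `"satterthwaite"` uses the Satterthwaite degrees of
#'   freedom, `"wald"` the normal approximation to the t statistic;
#'   `"auto"` (default) picks Wald when the residual degrees of freedom
#'   exceed 1500, where the two are numerically indistinguishable.
#' @return A list with `estimate` (fixed effect on the modelling scale),
#'   `p_raw`, `n_subjects`, `n_windows`, `singular`, `transform`; or `NULL`
#'   when fewer than 2 subjects contribute both levels.
#' @export
fit_cohort_model <- function(data, sqrt_transform = TRUE,
                             p_method = c("auto", "satterthwaite", "wald")) {
  p_method <- match.arg(p_method)
  lev <- setdiff(levels(droplevels(data$range)), "IR")
  if (length(lev) != 1) stop("data must contain IR plus exactly one other level")
  both <- tapply(data$range, data$subject_id,
                 function(r) all(c("IR", lev) %in% r))
  both <- names(both)[!is.na(both) & both]
  if (length(both) < 2) return(NULL)
  d <- data[data$subject_id %in% both, , drop = FALSE]
  if (sqrt_transform && any(d$value < 0)) {
    stop("square-root transform requires non-negative values")
  }
  d$y <- if (sqrt_transform) sqrt(d$value) else d$value
  d$range <- stats::relevel(droplevels(d$range), ref = "IR")
  df_resid <- nrow(d) - length(both) - 1
  if (p_method == "auto") {
    p_method <- if (df_resid > 1500) "wald" else "satterthwaite"
  }
  if (p_method == "satterthwaite") {
    fit <- lmerTest::lmer(y ~ range + (1 | subject_id), data = d, REML = FALSE)
    coefs <- summary(fit)$coefficients
    p <- coefs[2, "Pr(>|t|)"]
  } else {
    fit <- lme4::lmer(y ~ range + (1 | subject_id), data = d, REML = FALSE)
    coefs <- summary(fit)$coefficients
    p <- 2 * stats::pnorm(-abs(coefs[2, "t value"]))
  }
  list(estimate = coefs[2, "Estimate"],
       p_raw = p,
       n_subjects = length(both),
       n_windows = nrow(d),
       singular = lme4::isSingular(fit),
       transform = if (sqrt_transform) "square-root" else "none")
}

#' Fit all cohort models
#'
#' One mixed-effects fit per metric x contrast x period over the pooled
#' labeled series of all subjects, with BH-FDR applied across the metrics
#' within each contrast x period family.
#'
#' @param labeled_list List of `tg_labeled` series, one per subject.
#' @param config A [tg_config()] list.
#' @param metrics Metrics to model (default all 12).
#' @param contrasts Contrast levels to model.
#' @return Data frame with one row per fitted (or absent) model.
#' @export
cohort_models <- function(labeled_list, config = tg_config(),
                          metrics = TG_METRICS, contrasts = c("AR", "BR")) {
  pooled <- do.call(rbind, lapply(labeled_list, function(l) {
    data.frame(subject_id = attr(l, "subject_id"),
               period = l$period, range = l$range,
               l[, intersect(metrics, names(l)), drop = FALSE])
  }))
  rows <- list()
  for (per in c("daytime", "nighttime")) {
    for (ctr in contrasts) {
      sub <- pooled[pooled$period == per & pooled$range %in% c("IR", ctr), ,
                    drop = FALSE]
      for (metric in metrics) {
        d <- data.frame(subject_id = sub$subject_id, value = sub[[metric]],
                        range = factor(sub$range, levels = c("IR", ctr)))
        res <- fit_cohort_model(d, config$sqrt_transform)
        rows[[length(rows) + 1L]] <- data.frame(
          metric = metric, contrast = paste0(ctr, "-vs-IR"), period = per,
          estimate = if (is.null(res)) NA_real_ else res$estimate,
          p_raw = if (is.null(res)) NA_real_ else res$p_raw,
          n_subjects = if (is.null(res)) 0L else res$n_subjects,
          n_windows = if (is.null(res)) 0L else res$n_windows,
          singular = if (is.null(res)) NA else res$singular,
          transform = if (config$sqrt_transform) "square-root" else "none")
      }
    }
  }
  out <- do.call(rbind, rows)
  fam <- interaction(out$contrast, out$period, drop = TRUE)
  out$p_fdr <- NA_real_
  for (g in levels(fam)) {
    sel <- fam == g
    out$p_fdr[sel] <- bh_fdr(out$p_raw[sel])
  }
  out
}

#' Percentage of subjects with significant differences
#'
#' For each metric x contrast x period, the percentage of eligible subjects
#' (those exhibiting the contrast's non-IR level in that period, with both
#' groups at the minimum size) whose FDR-corrected p is below 0.05, plus
#' the split into moderate (0.01 <= p < 0.05) and strong (p < 0.01) tiers.
#'
#' @param comparisons Row-bound [compare_subject()] results across subjects.
#' @return Data frame with `metric`, `contrast`, `period`, `n_eligible`,
#'   `n_significant`, `pct_significant`, `pct_moderate`, `pct_strong`
#'   (`NA` percentages when no subject is eligible).
#' @export
summarize_significance <- function(comparisons) {
  key <- interaction(comparisons$metric, comparisons$contrast,
                     comparisons$period, drop = TRUE)
  rows <- lapply(split(comparisons, key), function(d) {
    elig <- d[d$n_alt >= 1, , drop = FALSE]   # subjects exhibiting the level
    n <- nrow(elig)
    sig <- sum(elig$p_fdr < 0.05, na.rm = TRUE)
    data.frame(metric = d$metric[1], contrast = d$contrast[1],
               period = d$period[1],
               n_eligible = n,
               n_significant = sig,
               pct_significant = if (n) 100 * sig / n else NA_real_,
               pct_moderate = if (n)
                 100 * sum(elig$tier == "moderate", na.rm = TRUE) / n else NA_real_,
               pct_strong = if (n)
                 100 * sum(elig$tier == "strong", na.rm = TRUE) / n else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
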