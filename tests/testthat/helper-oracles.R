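# Independent naive oracles and small fixture builders used across tests.

# Naive direct evaluation of the nine current-window metrics.
naive_current <- function(v, r1 = 36, r2 = 32) {
  m <- mean(v); s <- sd(v); md <- median(v)
  c(mean_T = m, median_T = md, SD_T = s,
    IQR_T = unname(quantile(v, 0.75) - quantile(v, 0.25)),
    CV_T = s / m,
    MAD_T = 1.4826 * sum(abs(v - md)) / length(v),
    J_T = 0.001 * (m + s)^2,
    M1_T = sum(abs(10 * log10(v / r1))^3) / length(v),
    M2_T = sum(abs(10 * log10(v / r2))^3) / length(v))
}

# Naive retrospective metrics at every prefix of a window list.
naive_retro <- function(cv, means) {
  t(vapply(seq_along(cv), function(i) {
    cm <- mean(cv[1:i])
    c(CV_T_mean = cm,
      CV_T_SD = sqrt(sum((cv[1:i] - cm)^2) / i),
      SD_T_hhmm = sqrt(sum((means[1:i] - mean(means[1:i]))^2) / i))
  }, numeric(3)))
}

# Exact two-sided rank-sum p-value by full enumeration of rank assignments
# (doubled one-sided tail, capped at 1 — the standard convention).
enum_ranksum_p <- function(ref, alt) {
  pooled <- c(ref, alt)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  m <- length(alt)
  w_obs <- sum(r[seq_along(alt) + length(ref)])
  ws <- combn(length(pooled), m, FUN = function(idx) sum(r[idx]))
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# Step-up BH adjustment straight from the formula min_{j >= i} m * p(j) / j.
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o]
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * sorted[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Write a two-column CSV in the deposit dialect and return its path.
write_csv_fixture <- function(ts, values, header = c("Timestamp", "Value")) {
  path <- tempfile(fileext = ".csv")
  writeLines(c(paste(header, collapse = ","),
               paste(ts, values, sep = ",")), path)
  path
}

# A 4 Hz temperature trace (as CSV -> temp_trace) covering [t0 - 300 s, t0 + extra]
make_temp_trace <- function(t0, n, values, dt = 0.25) {
  tm <- t0 + dt * (seq_len(n) - 1)
  path <- write_csv_fixture(format(tm, "%Y-%m-%d %H:%M:%OS2", tz = "UTC"),
                            sprintf("%.2f", values))
  read_temperature_csv(path, subject_id = "T")
}

make_cgm_trace <- function(tm, glucose) {
  path <- write_csv_fixture(format(tm, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
                            ifelse(is.na(glucose), "", sprintf("%g", glucose)))
  read_cgm_csv(path, subject_id = "T")
}

T0 <- as.POSIXct("2024-03-01 12:00:00", tz = "UTC")

# Null-cohort configuration: serially independent glucose (exchangeable
# labels), no defects, no temperature-glycemia coupling.
null_synth_config <- function(seed, n_subjects = 15, days = 2) {
  tg_synth_config(n_subjects = n_subjects, days = days, hypo_subjects = 0,
                  artifact_rate = 0, outlier_rate = 0,
                  temp_missing_pct = 0, cgm_missing_pct = 0,
                  cv_effect = 1, level_effect_day_c = 0,
                  retro_effect_c_per_h = 0,
                  iid_glucose = TRUE, seed = seed)
}

# Effect cohort: strong below-range variability coupling, daytime episodes
# frequent enough for >= 30 BR windows per subject.
effect_synth_config <- function(seed, n_subjects = 6, days = 2, cv_effect = 3) {
  tg_synth_config(n_subjects = n_subjects, days = days,
                  hypo_subjects = n_subjects,
                  hypo_rate_per_day = 3.5, hypo_duration_min = 50,
                  hypo_hours = c(8, 20),
                  artifact_rate = 0, outlier_rate = 0,
                  temp_missing_pct = 0, cgm_missing_pct = 0,
                  cv_effect = cv_effect, level_effect_day_c = 0,
                  retro_effect_c_per_h = 0, seed = seed)
}
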