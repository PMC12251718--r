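test_that("closed-form toy windows evaluate exactly", {
  # constant window at 32 with r2 = 32: all dispersion metrics vanish
  cm <- current_metrics(rep(32, 1200))
  expect_equal(cm$SD_T, 0)
  expect_equal(cm$IQR_T, 0)
  expect_equal(cm$CV_T, 0)
  expect_equal(cm$MAD_T, 0)
  expect_equal(cm$M2_T, 0)
  expect_equal(cm$J_T, 0.001 * 32^2)

  # constant window at the M1 reference
  expect_equal(current_metrics(rep(36, 1200))$M1_T, 0)

  # (31, 32, 33): hand-evaluated values
  toy <- current_metrics(c(31, 32, 33))
  expect_equal(toy$median_T, 32)
  expect_equal(toy$MAD_T, 1.4826 * 2 / 3)
  expect_equal(toy$SD_T, 1)
  expect_equal(toy$J_T, 0.001 * 33^2)
  expect_equal(toy$M2_T,
               mean(c(abs(10 * log10(31 / 32))^3, 0, abs(10 * log10(33 / 32))^3)))
  expect_equal(toy$M1_T,
               mean(abs(10 * log10(c(31, 32, 33) / 36))^3))
})

test_that("all metrics match the naive oracle on random windows", {
  set.seed(2024)
  for (rep_i in 1:100) {
    n <- sample(c(8, 24, 60), 1)
    v <- runif(n, 28.5, 35.5)
    got <- unlist(current_metrics(v))
    want <- naive_current(v)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("the literal M-value form reduces to 30 * mean |log10|", {
  v <- runif(50, 29, 35)
  lit <- current_metrics(v, m_value_form = "literal")
  expect_equal(lit$M2_T, 30 * mean(abs(log10(v / 32))), tolerance = 1e-12)
})

test_that("retrospective metrics follow the population-denominator definitions", {
  expect_equal(retrospective_cv(0.03), list(CV_T_mean = 0.03, CV_T_SD = 0))
  r <- retrospective_cv(c(0.02, 0.04))
  expect_equal(r$CV_T_mean, 0.03)
  expect_equal(r$CV_T_SD, 0.01)
  expect_equal(retrospective_cv(rep(0.7, 9))$CV_T_SD, 0)
  expect_error(retrospective_cv(numeric()), "empty")

  expect_equal(sd_hhmm(32), 0)
  expect_equal(sd_hhmm(c(32, 34)), 1)
  expect_equal(sd_hhmm(rep(33.3, 5)), 0)
  expect_error(sd_hhmm(numeric()), "empty")

  # equal-length windows: grand mean of all samples == mean of window means
  set.seed(4)
  x <- matrix(runif(1200 * 6, 30, 34), nrow = 1200)
  expect_equal(mean(x), mean(colMeans(x)), tolerance = 1e-12)
  expect_equal(sd_hhmm(colMeans(x), m = mean(x)), sd_hhmm(colMeans(x)),
               tolerance = 1e-12)
})

series_from_matrix <- function(x, t0 = T0, config = tg_config()) {
  k <- ncol(x)
  ret <- list(subject_id = "S", cgm_time = t0 + 300 * (seq_len(k) - 1),
              glucose = rep(100, k), samples = x)
  compute_metric_series(ret, config)
}

test_that("streaming retrospective metrics equal batch recomputation", {
  set.seed(11)
  x <- matrix(runif(1200 * 40, 30, 34), nrow = 1200)
  ser <- series_from_matrix(x)
  want <- naive_retro(ser$CV_T, ser$mean_T)
  expect_equal(ser$CV_T_mean, want[, "CV_T_mean"], tolerance = 1e-9)
  expect_equal(ser$CV_T_SD, want[, "CV_T_SD"], tolerance = 1e-9)
  expect_equal(ser$SD_T_hhmm, want[, "SD_T_hhmm"], tolerance = 1e-9)
  # explicit per-window equivalence with the scalar operations
  i <- 17
  rc <- retrospective_cv(ser$CV_T[1:i])
  expect_equal(ser$CV_T_mean[i], rc$CV_T_mean, tolerance = 1e-9)
  expect_equal(ser$CV_T_SD[i], rc$CV_T_SD, tolerance = 1e-9)
  expect_equal(ser$SD_T_hhmm[i], sd_hhmm(ser$mean_T[1:i]), tolerance = 1e-9)
})

test_that("a single retained window has zero retrospective dispersion", {
  x <- matrix(runif(1200, 31, 33), ncol = 1)
  ser <- series_from_matrix(x)
  expect_equal(nrow(ser), 1)
  expect_equal(ser$CV_T_SD, 0)
  expect_equal(ser$SD_T_hhmm, 0)
  expect_equal(ser$CV_T_mean, ser$CV_T)
})

test_that("the series is chronology-enforced and deterministic", {
  set.seed(3)
  x <- matrix(runif(1200 * 10, 30, 34), nrow = 1200)
  k <- ncol(x)
  tm <- T0 + 300 * (seq_len(k) - 1)
  perm <- sample(k)
  a <- compute_metric_series(list(subject_id = "S", cgm_time = tm,
                                  glucose = rep(100, k), samples = x))
  b <- compute_metric_series(list(subject_id = "S", cgm_time = tm[perm],
                                  glucose = rep(100, k),
                                  samples = x[, perm, drop = FALSE]))
  expect_equal(a, b)
})

test_that("adding a constant shifts location metrics and transforms the rest consistently", {
  set.seed(5)
  v <- runif(600, 30, 33)
  c0 <- 1.75
  a <- current_metrics(v)
  b <- current_metrics(v + c0)
  expect_equal(b$mean_T, a$mean_T + c0)
  expect_equal(b$median_T, a$median_T + c0)
  expect_equal(b$SD_T, a$SD_T)
  expect_equal(b$IQR_T, a$IQR_T)
  expect_equal(b$MAD_T, a$MAD_T)
  expect_equal(b$CV_T, a$SD_T / (a$mean_T + c0))
  expect_equal(b$J_T, 0.001 * (a$mean_T + c0 + a$SD_T)^2)
  expect_equal(unlist(b[c("M1_T", "M2_T")]), naive_current(v + c0)[c("M1_T", "M2_T")],
               tolerance = 1e-12)
})

test_that("M-values vanish only at the reference and grow monotonically away from it", {
  lv <- seq(32, 35, by = 0.5)
  m2 <- vapply(lv, function(l) current_metrics(rep(l, 10))$M2_T, 0)
  expect_equal(m2[1], 0)
  expect_true(all(diff(m2) > 0))
  dn <- vapply(seq(32, 29, by = -0.5), function(l) current_metrics(rep(l, 10))$M2_T, 0)
  expect_true(all(diff(dn) > 0))
  expect_gt(current_metrics(c(rep(32, 9), 32.5))$M2_T, 0)
})

test_that("daily reset restarts the retrospective accumulators", {
  set.seed(6)
  k <- 12
  x <- matrix(runif(1200 * k, 30, 34), nrow = 1200)
  tm <- T0 + 21600 * (seq_len(k) - 1)    # 6-hour cadence spans two days
  cfg <- tg_config(reset_daily = TRUE)
  ret <- list(subject_id = "S", cgm_time = tm, glucose = rep(100, k), samples = x)
  ser <- compute_metric_series(ret, cfg)
  first_day2 <- which(format(tm, "%Y-%m-%d") != format(tm[1], "%Y-%m-%d"))[1]
  expect_equal(ser$CV_T_SD[first_day2], 0)
  expect_equal(ser$SD_T_hhmm[first_day2], 0)
  expect_equal(ser$CV_T_mean[first_day2], ser$CV_T[first_day2])
})

test_that("non-finite samples are rejected", {
  expect_error(current_metrics(c(rep(32, 10), NA)), "non-finite")
})
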