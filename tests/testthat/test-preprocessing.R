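# Fixtures: a 4 Hz stream starting exactly one window before the first CGM
# sample, so window k of the CGM grid owns samples (t_k - 300, t_k].
make_pair <- function(n_cgm, temp_values, glucose = rep(100, n_cgm)) {
  t0 <- T0
  cgm <- make_cgm_trace(t0 + 300 * (seq_len(n_cgm) - 1), glucose)
  n_t <- length(temp_values)
  temp <- make_temp_trace(t0 - 300 + 0.25, n_t, temp_values)
  list(temp = temp, cgm = cgm)
}

test_that("subject exclusion is strict at the 20% threshold", {
  tm <- T0 + 300 * (0:9)                     # expected = 10
  keep20 <- summarize_completeness(make_cgm_trace(tm, c(rep(100, 8), NA, NA)))
  expect_equal(keep20$percent_missing_cgm, 20)
  expect_false(exclude_subject(keep20)$exclude)

  tm4 <- T0 + 300 * (0:3)                    # expected = 4, observed 3 -> 25%
  excl <- summarize_completeness(make_cgm_trace(tm4, c(100, NA, 100, 100)))
  expect_equal(excl$percent_missing_cgm, 25)
  expect_true(exclude_subject(excl)$exclude)

  expect_false(exclude_subject(summarize_completeness(
    make_cgm_trace(tm, rep(100, 10))))$exclude)
})

test_that("a fully sampled backward window holds exactly 1200 samples with half-open bounds", {
  # distinctive endpoint values: 11 at t-300 (excluded), 99 at t (included)
  v <- rep(32, 2400)
  v[1200] <- 11      # sample at exactly t1 - 300 for the second CGM sample
  v[2400] <- 99      # sample at exactly t1
  pair <- make_pair(2, v)
  w <- align_windows(pair$temp, pair$cgm)
  expect_equal(w$verdict, c("candidate", "candidate"))
  expect_equal(nrow(w$samples), 5 * 60 * 4)
  expect_equal(ncol(w$samples), 2)
  win2 <- w$samples[, 2]
  expect_equal(win2[length(win2)], 99)       # boundary t included
  expect_false(11 %in% win2)                 # boundary t - 300 excluded
  expect_true(11 %in% w$samples[, 1])        # it belongs to the earlier window
})

test_that("windows with missing glucose or incomplete temperature are discarded first", {
  v <- rep(32, 2400)
  pair <- make_pair(2, v, glucose = c(100, NA))
  w <- align_windows(pair$temp, pair$cgm)
  expect_equal(w$verdict[2], "discarded_missing_glucose")

  # drop 7 samples from the second window -> 1193 < 1200
  tmp <- pair$temp[-c(1500:1506), ]
  class(tmp) <- class(pair$temp)
  attr(tmp, "subject_id") <- "T"
  w2 <- align_windows(tmp, make_cgm_trace(T0 + 300 * (0:1), c(100, 100)))
  expect_equal(w2$verdict, c("candidate", "discarded_missing_temperature"))

  # missing glucose takes precedence even when temperature is also missing
  w3 <- align_windows(tmp, pair$cgm)
  expect_equal(w3$verdict[2], "discarded_missing_glucose")

  # empty temperature trace -> everything missing temperature
  w4 <- align_windows(pair$temp[0, ], make_cgm_trace(T0 + 300 * (0:1), c(100, 100)))
  expect_true(all(w4$verdict == "discarded_missing_temperature"))
})

test_that("artifact and outlier screening follow the strict-inequality rules", {
  expect_equal(screen_window(c(rep(32, 1199), 27.5)), "discarded_artifact")
  expect_equal(screen_window(rep(28, 1200)), "retained")      # 28.00 is not < 28
  expect_equal(screen_window(rep(32, 1200)), "retained")      # SD = 0 band

  # one sample at mean + 6 SD of the original draw exceeds the recomputed
  # mean + 5 SD bound and is flagged
  set.seed(31)
  base <- rnorm(1199, 33, 0.1)
  spike <- mean(base) + 6 * sd(base)
  v <- c(base, spike)
  expect_gt(spike, mean(v) + 5 * sd(v))
  expect_equal(screen_window(v), "discarded_outlier")

  # a sample at exactly mean + 5 SD is inside the closed band
  exact <- 35 + c(-5, rep(0, 49), 5)         # mean 35, sd exactly 1, min 30
  expect_equal(sd(exact), 1)
  expect_equal(screen_window(exact), "retained")

  # artifact takes precedence over outlier
  both <- c(rep(32, 1198), 27, 40)
  expect_equal(screen_window(both), "discarded_artifact")
})

test_that("single-window and vectorized screening agree", {
  set.seed(77)
  cfg <- tg_config()
  x <- matrix(rnorm(1200 * 50, 32, 0.5), nrow = 1200)
  x[1, 3] <- 27      # artifact
  x[5, 9] <- 32 + 8 * 0.5
  pair <- make_pair(50, as.vector(x))
  pp <- preprocess_subject(pair$temp, pair$cgm, cfg)
  w <- align_windows(pair$temp, pair$cgm, cfg)
  single <- vapply(seq_len(50), function(j)
    screen_window(w$samples[, j], cfg$artifact_floor_c,
                  cfg$outlier_sd_multiplier, cfg$sd_denominator), "")
  batch <- screen_windows(w, cfg)$verdict
  expect_identical(batch, single)
})

test_that("preprocessing conserves windows and is idempotent", {
  cfg <- tg_synth_config(n_subjects = 1, days = 1, hypo_subjects = 0, seed = 101)
  sub <- generate_cohort(cfg)[[1]]
  pp <- preprocess_subject(sub$temp, sub$cgm)
  r <- pp$report
  expect_equal(r$windows_retained + sum(r$discard_counts), r$windows_total)
  expect_equal(r$windows_total, nrow(sub$cgm))

  # idempotence: re-screening the retained windows retains them all
  ret <- retained_windows(pp$windows)
  verd <- vapply(seq_len(ncol(ret$samples)), function(j)
    screen_window(ret$samples[, j]), "")
  expect_true(all(verd == "retained"))
})

test_that("a defect-free synthetic subject retains 100% of full windows", {
  cfg <- null_synth_config(seed = 55, n_subjects = 1, days = 1)
  sub <- generate_cohort(cfg)[[1]]
  pp <- preprocess_subject(sub$temp, sub$cgm)
  expect_equal(pp$report$percent_retained, 100)
})

test_that("a trace entirely below the artifact floor retains nothing but conserves totals", {
  pair <- make_pair(3, rep(26, 3600))
  pp <- preprocess_subject(pair$temp, pair$cgm)
  expect_equal(pp$report$windows_retained, 0)
  expect_equal(sum(pp$report$discard_counts), 3)
  expect_equal(unname(pp$report$discard_counts[["discarded_artifact"]]), 3)
})
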