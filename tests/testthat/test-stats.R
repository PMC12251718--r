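test_that("rank-sum p-values agree with exact enumeration for all small group sizes", {
  set.seed(101)
  for (n in 2:6) {
    for (m in 2:6) {
      ref <- runif(n); alt <- runif(m) + runif(1, -0.5, 0.5)
      res <- wilcoxon_compare(ref, alt, min_group_size = 2)
      expect_equal(res$p_raw, enum_ranksum_p(ref, alt), tolerance = 1e-12,
                   info = sprintf("n=%d m=%d", n, m))
    }
  }
  # complete separation at n = m = 4: doubled 1/C(8,4) tail
  sep <- wilcoxon_compare(1:4, 10:13)
  expect_equal(sep$p_raw, 2 / 70, tolerance = 1e-12)
})

test_that("rank-sum comparison handles identical, tied and undersized groups", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  res <- wilcoxon_compare(x, x)          # exchangeable -> p near 1 (midranks)
  expect_gt(res$p_raw, 0.9)
  expect_null(wilcoxon_compare(1:10, numeric()))
  expect_null(wilcoxon_compare(1:10, 1:3))
  got <- wilcoxon_compare(c(1, 2, 3, 4, 10), c(2, 3, 9, 11))
  expect_true(is.finite(got$p_raw))
  # group summaries are the quartile triplet used in the report tables
  expect_equal(got$ref_median, median(c(1, 2, 3, 4, 10)))
  expect_equal(got$alt_q25, unname(quantile(c(2, 3, 9, 11), 0.25)))
})

test_that("BH adjustment matches the step-up formula and its invariances", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.013), 0.013)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(3:12, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, naive_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm]), adj[perm])
  }
  expect_error(bh_fdr(c(0.5, 1.2)))
})

test_that("Lilliefors screening rejects rarely under normality and reliably under skew", {
  set.seed(33)
  p_norm <- replicate(200, lilliefors_test(rnorm(300)))
  expect_lt(mean(p_norm < 0.05), 0.10)
  p_skew <- replicate(200, lilliefors_test(rnorm(300)^2))
  expect_gt(mean(p_skew < 0.05), 0.95)
  expect_true(is.na(lilliefors_test(rep(5, 100))))
  expect_true(is.na(lilliefors_test(c(1, 2, 3))))
})

sim_cohort_values <- function(n_subj, n_per, shift_sd = 0) {
  subj <- rep(sprintf("P%02d", seq_len(n_subj)), each = n_per)
  lev <- factor(rep_len(c("IR", "AR"), n_subj * n_per), levels = c("IR", "AR"))
  base <- rep(rnorm(n_subj, 10, 0.5), each = n_per)
  val <- base + rnorm(n_subj * n_per) + shift_sd * (lev == "AR")
  data.frame(subject_id = subj, value = val^2, range = lev)  # sqrt undoes this
}

test_that("the mixed-effects model is calibrated under the null and powered under a shift", {
  set.seed(44)
  p_null <- replicate(150, fit_cohort_model(sim_cohort_values(10, 40),
                                            p_method = "wald")$p_raw)
  expect_gte(mean(p_null < 0.05), 0.015)
  expect_lte(mean(p_null < 0.05), 0.10)

  fits <- replicate(50, {
    f <- fit_cohort_model(sim_cohort_values(10, 40, shift_sd = 1),
                          p_method = "wald")
    c(f$p_raw, f$estimate)
  })
  expect_gte(mean(fits[1, ] < 0.05), 0.8)
  expect_gte(mean(fits[2, ] > 0), 0.95)   # sign of the injected effect
})

test_that("Satterthwaite and Wald fixed-effect p-values agree at large df", {
  set.seed(45)
  d <- sim_cohort_values(8, 120, shift_sd = 0.1)
  ps <- fit_cohort_model(d, p_method = "satterthwaite")$p_raw
  pw <- fit_cohort_model(d, p_method = "wald")$p_raw
  expect_equal(ps, pw, tolerance = 1e-3)
})

test_that("degenerate cohort-model inputs are absent or flagged, not fabricated", {
  set.seed(46)
  one <- sim_cohort_values(1, 30)
  expect_null(fit_cohort_model(one))
  d <- sim_cohort_values(5, 30)
  d$range <- factor("IR", levels = c("IR", "AR"))
  expect_error(fit_cohort_model(rbind(d)), "exactly one other level")
  neg <- sim_cohort_values(5, 30)
  neg$value[1] <- -1
  expect_error(fit_cohort_model(neg), "non-negative")
})

test_that("significance summaries count eligible subjects only", {
  mk <- function(sid, p_fdr, n_alt) {
    data.frame(subject_id = sid, metric = "CV_T_SD", contrast = "BR-vs-IR",
               period = "daytime", n_ref = 100, n_alt = n_alt,
               ref_median = 1, ref_q25 = 1, ref_q75 = 1,
               alt_median = 1, alt_q25 = 1, alt_q75 = 1,
               p_raw = p_fdr, p_fdr = p_fdr,
               tier = ifelse(is.na(p_fdr), NA_character_,
                             ifelse(p_fdr < 0.01, "strong",
                                    ifelse(p_fdr < 0.05, "moderate", "none"))))
  }
  four_of_four <- do.call(rbind, lapply(1:4, function(i) mk(i, 0.003, 30)))
  s <- summarize_significance(four_of_four)
  expect_equal(s$pct_significant, 100)
  expect_equal(s$pct_strong, 100)

  two_of_four <- do.call(rbind, list(mk(1, 0.01, 30), mk(2, 0.02, 30),
                                     mk(3, 0.5, 30), mk(4, 0.9, 30)))
  expect_equal(summarize_significance(two_of_four)$pct_significant, 50)

  # subjects without the glycemic level are not eligible
  with_absent <- rbind(two_of_four, mk(5, NA, 0), mk(6, NA, 0))
  expect_equal(summarize_significance(with_absent)$n_eligible, 4)
  expect_equal(summarize_significance(with_absent)$pct_significant, 50)

  none <- rbind(mk(1, NA, 0), mk(2, NA, 0))
  expect_true(is.na(summarize_significance(none)$pct_significant))
})
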