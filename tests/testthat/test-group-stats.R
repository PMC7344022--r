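test_that("pearson correlation matches the textbook formulas", {
  set.seed(41)
  x <- rnorm(200); y <- 0.4 * x + rnorm(200)
  got <- pearson_cor(x, y)
  want <- hand_pearson(x, y)
  expect_equal(got$r, want$r, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
  expect_equal(pearson_cor(x, x)$r, 1)
  expect_equal(pearson_cor(x, -x + 5)$r, -1)
  expect_error(pearson_cor(rep(1, 10), rnorm(10)), "CONSTANT_INPUT")
  expect_error(pearson_cor(1:4, 1:5), "unequal")
})

test_that("correlation matrix is symmetric, unit-diagonal and PSD", {
  cfg <- cohort_config(n_subjects = 30, seed = 42)
  tb <- simulate_cohort_table(cfg)$table
  cm <- correlation_matrix(tb, condition = "rest")
  expect_equal(cm$values, t(cm$values))
  expect_equal(unname(diag(cm$values)), rep(1, ncol(tb$mean)))
  expect_true(all(cm$values >= -1 & cm$values <= 1))
  expect_gte(min(eigen(cm$values, symmetric = TRUE)$values), -1e-8)
  expect_equal(cm$n_scans, 60)
})

test_that("identical columns give an all-ones matrix; noise stays near zero", {
  cfg <- cohort_config(n_subjects = 10, seed = 43)
  tb <- simulate_cohort_table(cfg)$table
  tb$mean[] <- tb$mean[, 1]
  cm <- correlation_matrix(tb, condition = "task")
  expect_true(all(abs(cm$values - 1) < 1e-12))
  # independent iid columns: small off-diagonals on 200 rows
  tb2 <- simulate_cohort_table(cohort_config(n_subjects = 50, seed = 44,
                                             subject_sd = 0,
                                             shared_scan_sd = 0))$table
  set.seed(45)
  tb2$mean[] <- rnorm(length(tb2$mean))
  cm2 <- correlation_matrix(tb2, condition = NULL)
  off <- cm2$values[upper.tri(cm2$values)]
  expect_lt(mean(abs(off)), 0.15)
})

test_that("listwise deletion governs missing cells, few scans error", {
  cfg <- cohort_config(n_subjects = 6, seed = 46)
  tb <- simulate_cohort_table(cfg)$table
  rest_rows <- which(tb$scans$condition == "rest")
  tb$mean[rest_rows[1], 3] <- NA
  cm <- correlation_matrix(tb, condition = "rest")
  expect_equal(cm$n_scans, length(rest_rows) - 1)
  tb$mean[rest_rows, 2] <- NA
  expect_error(correlation_matrix(tb, condition = "rest"), "TOO_FEW_SCANS")
})

test_that("shared-factor strength raises between-region correlations", {
  # planted one-factor structure: off-diagonals grow with the factor share
  mean_off <- sapply(c(0, 0.02, 0.05), function(s) {
    tb <- simulate_cohort_table(cohort_config(n_subjects = 50, seed = 47,
                                              subject_sd = 0,
                                              shared_scan_sd = s))$table
    cm <- correlation_matrix(tb, condition = "rest")
    mean(cm$values[upper.tri(cm$values)])
  })
  expect_true(all(diff(mean_off) > 0))
})

test_that("paired t-test agrees with the closed-form computation", {
  set.seed(48)
  rest <- rnorm(200, mean = 1.1, sd = 0.1)
  task <- rest - rnorm(200, mean = 0.05, sd = 0.08)
  got <- paired_ttest(rest, task, n_tests = 7)
  d <- rest - task
  t_ref <- mean(d) / (sd(d) / sqrt(200))
  p_ref <- 2 * pt(-abs(t_ref), 199)
  expect_equal(got$t_stat, t_ref, tolerance = 1e-10)
  expect_equal(got$df, 199)
  expect_equal(got$p_raw, p_ref, tolerance = 1e-10)
  expect_equal(got$p_adjusted, min(1, 7 * p_ref), tolerance = 1e-10)
  expect_equal(got$mean_diff, mean(d), tolerance = 1e-12)
})

test_that("degenerate paired differences are sentinels, not numbers", {
  # alternating +d/-d: zero mean difference, t exactly 0
  r <- c(1.2, 1.0, 1.2, 1.0); t <- c(1.0, 1.2, 1.0, 1.2)
  got <- paired_ttest(r, t)
  expect_equal(got$t_stat, 0)
  expect_equal(got$p_raw, 1)
  # constant nonzero difference: zero-variance sentinel
  got2 <- paired_ttest(c(1, 2, 3, 4), c(0.5, 1.5, 2.5, 3.5))
  expect_true(got2$degenerate)
  expect_true(is.na(got2$t_stat))
  expect_equal(got2$mean_diff, 0.5)
})

test_that("bonferroni adjustment is the capped product and order-preserving", {
  expect_equal(bonferroni(0.01, 1), 0.01)
  expect_equal(bonferroni(c(0.01, 0.2, 0.5, 0.9)), c(0.04, 0.8, 1, 1))
  expect_equal(bonferroni(0.02, 7), 0.14)
  set.seed(49)
  p <- sort(runif(20))
  expect_true(all(diff(bonferroni(p)) >= 0))
  expect_equal(bonferroni(p), p.adjust(p, "bonferroni"))
  expect_error(bonferroni(c(0.5, 1.2)), "OUT_OF_RANGE")
})

test_that("two-factor ANOVA reproduces hand-computed sums of squares", {
  # 2 x 2 with 3 observations per cell
  y <- c(4.1, 3.9, 4.3,   5.0, 5.2, 4.9,
         3.2, 3.4, 3.1,   3.9, 4.1, 4.2)
  fa <- rep(c("a1", "a2"), each = 6)
  fb <- rep(rep(c("b1", "b2"), each = 3), 2)
  got <- two_factor_anova(y, fa, fb)
  want <- hand_anova2(y, fa, fb)
  expect_equal(got$ss[1:4], want$ss, tolerance = 1e-10)
  expect_equal(got$df[1:4], want$df)
  expect_equal(got$f[1:3], want$f[1:3], tolerance = 1e-10)
  expect_equal(got$p[1:3], want$p[1:3], tolerance = 1e-10)
  # partition invariant
  expect_equal(sum(got$ss[1:4]), got$ss[5], tolerance = 1e-10)
  expect_equal(sum(got$df[1:4]), got$df[5])
})

test_that("ANOVA degenerate and unbalanced inputs follow the contract", {
  y <- rep(2.5, 12)
  fa <- rep(c("x", "y"), 6); fb <- rep(c("u", "u", "v", "v"), 3)
  got <- two_factor_anova(y, fa, fb)
  expect_true(all(got$ss == 0))
  expect_true(all(is.na(got$f)))
  expect_error(two_factor_anova(rnorm(5), c(1, 1, 1, 2, 2),
                                c(1, 2, 1, 2, 1)), "UNBALANCED_DESIGN")
})

test_that("ANOVA interaction p is calibrated under additive truth", {
  set.seed(50)
  n_rej <- 0L; n_rep <- 400L
  for (i in seq_len(n_rep)) {
    fa <- rep(c(0, 1), each = 20)
    fb <- rep(rep(c(0, 1), each = 10), 2)
    y <- 0.5 * fa + 0.3 * fb + rnorm(40)
    out <- two_factor_anova(y, fa, fb)
    if (out$p[3] < 0.05) n_rej <- n_rej + 1L
  }
  expect_gt(n_rej / n_rep, 0.02)
  expect_lt(n_rej / n_rep, 0.08)
})

test_that("ICC(3,1) matches the hand decomposition and its fixed points", {
  set.seed(51)
  y1 <- rnorm(30); y2 <- 0.6 * y1 + rnorm(30, sd = 0.5)
  got <- icc_3_1(y1, y2)
  expect_equal(got$icc, hand_icc31(y1, y2), tolerance = 1e-10)
  expect_equal(icc_3_1(y1, y1)$icc, 1, tolerance = 1e-12)
  # consistency form is insensitive to a fixed shift between scans
  expect_equal(icc_3_1(y1, y1 + 3.7)$icc, 1, tolerance = 1e-10)
  expect_error(icc_3_1(1:2, 1:2), "TOO_FEW_SUBJECTS")
})

test_that("ICC recovers a planted variance-component reliability", {
  rho <- 0.5
  set.seed(52)
  est <- replicate(60, {
    s <- rnorm(150, sd = sqrt(rho))
    icc_3_1(s + rnorm(150, sd = sqrt(1 - rho)),
            s + rnorm(150, sd = sqrt(1 - rho)))$icc
  })
  expect_lt(abs(mean(est) - rho), 0.05)
})

test_that("scan consistency reports per-region reliability and group r", {
  cfg <- cohort_config(n_subjects = 25, seed = 53)
  tb <- simulate_cohort_table(cfg)$table
  r1 <- tb$scans$condition == "rest" & tb$scans$scan_index == 1
  r2 <- tb$scans$condition == "rest" & tb$scans$scan_index == 2
  sub1 <- sampenmap:::subset_roi_table(tb, r1)
  sub2 <- sampenmap:::subset_roi_table(tb, r2)
  cons <- scan_consistency(sub1, sub2)
  expect_equal(nrow(cons$per_roi), ncol(tb$mean))
  # identical tables: perfect consistency
  same <- scan_consistency(sub1, sub1)
  expect_true(all(abs(same$per_roi$icc - 1) < 1e-10))
  expect_true(all(abs(same$per_roi$r - 1) < 1e-10))
  expect_equal(same$group_r, 1, tolerance = 1e-12)
  # mismatched subjects rejected
  sub3 <- sub2; sub3$scans$subject_id <- rev(sub3$scans$subject_id)
  expect_error(scan_consistency(sub1, sub3), "SUBJECT_MISMATCH")
})

test_that("zero subject effect drives scan-consistency ICC toward zero", {
  set.seed(54)
  iccs <- replicate(40, {
    y1 <- rnorm(60); y2 <- rnorm(60)  # independent regeneration
    icc_3_1(y1, y2)$icc
  })
  expect_lt(abs(mean(iccs)), 0.05)
})
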