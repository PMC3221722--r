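test_that("well-separated measurement probes are all detected", {
  ann <- tiny_annotation(n_sets = 5, probes_per_set = 4, n_bg = 30)
  set.seed(1)
  n_meas <- sum(ann$role == "measurement")
  v <- c(stats::runif(n_meas, 1000, 2000), stats::runif(30, 10, 20))
  m <- matrix(v, dimnames = list(ann$probe_id, NULL))
  colnames(m) <- "A1"
  qc <- qc_report(m, ann, alpha = 0.06)
  expect_equal(qc$n_detected_probes, n_meas)
  expect_equal(qc$n_detected_probesets, 5)
  expect_gt(qc$mean_intensity, qc$mean_background)
})

test_that("measurement probes sharing the background distribution detect at ~alpha", {
  ann <- tiny_annotation(n_sets = 100, probes_per_set = 4, n_bg = 200)
  set.seed(2)
  v <- stats::rlnorm(nrow(ann), 5, 1)
  m <- matrix(v, dimnames = list(ann$probe_id, NULL)); colnames(m) <- "A1"
  qc <- qc_report(m, ann, alpha = 0.06)
  expect_lt(abs(qc$n_detected_probes / 400 - 0.06), 0.04)
  expect_lt(qc$n_detected_probesets, 100 * 0.2)
})

test_that("detection is monotone in alpha and total at alpha = 1", {
  coh <- generate_cohort(small_config(seed = 4), 4)
  alphas <- c(0.01, 0.06, 0.2, 1)
  counts <- vapply(alphas, function(a) {
    qc_report(coh$intensities, coh$annotation, alpha = a)$n_detected_probes[1]
  }, 1)
  expect_true(all(diff(counts) >= 0))
  n_meas <- sum(coh$annotation$role == "measurement")
  expect_equal(counts[4], n_meas)
  stripped <- coh$annotation[coh$annotation$role == "measurement", ]
  expect_error(qc_report(coh$intensities[stripped$probe_id, ], stripped),
               "background")
})

test_that("rank-sum detection matches exhaustive enumeration on small inputs", {
  set.seed(3)
  for (i in 1:20) {
    nx <- sample(2:5, 1); ny <- sample(4:12, 1)
    x <- sample(1:6, nx, replace = TRUE)  # deliberately tied values
    y <- sample(1:6, ny, replace = TRUE)
    got <- rank_sum_greater(x, y)$p_value
    expect_equal(got, oracle_ranksum_exact(x, y), tolerance = 1e-12)
  }
  # against wilcox.test exact p on tie-free data
  for (i in 1:10) {
    x <- stats::rnorm(4, 1); y <- stats::rnorm(10)
    got <- rank_sum_greater(x, y)$p_value
    ref <- stats::wilcox.test(x, y, alternative = "greater",
                              exact = TRUE)$p.value
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("self-self correlations behave as Pearson on the log2 scale", {
  set.seed(4)
  m <- matrix(stats::rlnorm(10000 * 2, 5, 1), 10000, 2,
              dimnames = list(NULL, c("A1", "A2")))
  m[, 2] <- m[, 1]
  r <- self_self_correlation(m)
  expect_equal(r["A1", "A2"], 1, tolerance = 1e-12)

  m[, 2] <- 2 * m[, 1]  # log2 shift leaves Pearson r untouched
  r <- self_self_correlation(m)
  expect_equal(r["A1", "A2"], 1, tolerance = 1e-12)

  m2 <- matrix(2^stats::rnorm(10000 * 2), 10000, 2,
               dimnames = list(NULL, c("A1", "A2")))
  expect_lt(abs(self_self_correlation(m2)["A1", "A2"]), 0.05)

  const <- cbind(A1 = rep(4, 10), A2 = 1:10 * 1.0)
  expect_error(self_self_correlation(const), "constant")
})

test_that("regress reproduces hand OLS and the exact-fit limit", {
  r <- regress(c(1, 2, 2), c(1, 2, 3))
  expect_equal(r$slope, 0.5, tolerance = 1e-12)
  expect_equal(r$r_squared, 0.75, tolerance = 1e-12)

  x <- 1:10; y <- 3 + 2 * x
  rf <- suppressWarnings(regress(y, x))  # lm warns on an exact fit
  expect_equal(rf$r_squared, 1, tolerance = 1e-10)
  expect_lt(rf$p_value, 1e-12)

  expect_error(regress(1:5, rep(2, 5)), "constant")
  expect_error(regress(1:2, 1:2), "n >= 3")
})

test_that("regress matches the normal-equations oracle on random instances", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    x <- stats::rnorm(n); y <- stats::rnorm(n, 0.5 * x)
    got <- regress(y, x); ref <- oracle_ols(y, x)
    expect_equal(got$slope, ref$slope, tolerance = 1e-8)
    expect_equal(got$se, ref$se, tolerance = 1e-8)
    expect_equal(got$p_value, ref$p, tolerance = 1e-8)
    expect_equal(got$r_squared, ref$r2, tolerance = 1e-8)
  }
})

test_that("regression p-values are uniform under the null", {
  set.seed(6)
  ps <- vapply(1:500, function(i) {
    regress(stats::rnorm(100), stats::rnorm(100))$p_value
  }, 1)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("compare_groups reproduces hand computations and the t^2 = F identity", {
  r <- compare_groups(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(r$statistic, -3 * sqrt(3 / 2), tolerance = 1e-10)
  expect_equal(r$df, 4)

  # two-group F equals t^2
  set.seed(7)
  v <- stats::rnorm(12); g <- rep(c("a", "b"), each = 6)
  tt <- compare_groups(v, g)
  f2 <- oracle_anova_f(v, g)
  expect_equal(tt$statistic^2, f2$f, tolerance = 1e-10)
  expect_equal(tt$p_value, f2$p, tolerance = 1e-10)

  same <- compare_groups(rep(2, 9), rep(c("a", "b", "c"), each = 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(compare_groups(1:5, c("a", "a", "a", "a", "b")), "n < 2")
})

test_that("compare_groups matches the textbook oracles on random instances", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    v <- stats::rnorm(3 * n); g <- rep(letters[1:3], each = n)
    got <- compare_groups(v, g); ref <- oracle_anova_f(v, g)
    expect_equal(got$statistic, ref$f, tolerance = 1e-8)
    expect_equal(got$p_value, ref$p, tolerance = 1e-8)

    a <- stats::rnorm(n); b <- stats::rnorm(n, 0.3)
    got2 <- compare_groups(c(a, b), rep(c("x", "y"), each = n))
    ref2 <- oracle_pooled_t(a, b)
    expect_equal(got2$statistic, ref2$t, tolerance = 1e-8)
    expect_equal(got2$p_value, ref2$p, tolerance = 1e-8)
  }
})

test_that("correlation decays with input deviation, not with ATP or lot", {
  coh <- generate_cohort(sim_config(seed = 7), 4)
  neg <- 0
  for (s in 1:5) {
    reps <- generate_condition_replicates(coh, "S001",
      lapply(c(80, 160, 400, 640), function(ng) c(rna_input_ng = ng)),
      seed = s)
    cv <- correlation_vs_input_deviation(reps$intensities, reps$samples,
                                         annotation = coh$annotation)
    neg <- neg + (cv$slope < 0)
  }
  expect_gte(neg, 4)

  atp <- generate_condition_replicates(coh, "S001",
    lapply(c("1:50", "1:150", "1:500"), function(d) c(atp_dilution = d)))
  cva <- correlation_vs_input_deviation(atp$intensities, atp$samples,
                                        covariate = "atp_dilution",
                                        annotation = coh$annotation)
  # 95% CI (t quantile at n - 2 df) covers zero
  expect_lte(abs(cva$slope), stats::qt(0.975, cva$n - 2) * cva$se)

  lot <- generate_condition_replicates(coh, "S001",
    lapply(c("A", "A", "A", "B", "B", "B"), function(l) c(lot_id = l)))
  cvl <- correlation_vs_input_deviation(lot$intensities, lot$samples,
                                        covariate = "lot_id",
                                        deviation = "mismatch",
                                        annotation = coh$annotation)
  expect_lte(abs(cvl$slope), stats::qt(0.975, cvl$n - 2) * cvl$se)
})

test_that("degenerate pair designs are rejected", {
  coh <- generate_cohort(small_config(seed = 9), 4)
  reps <- generate_condition_replicates(coh, "S001",
    list(c(rna_input_ng = 600), c(rna_input_ng = 600), c(rna_input_ng = 600)))
  expect_error(
    correlation_vs_input_deviation(reps$intensities, reps$samples,
                                   annotation = coh$annotation),
    "constant")
})

test_that("a constructed monotone-decreasing correlation gives a negative slope", {
  # hand-built: r decreasing exactly in deviation
  r <- c(0.99, 0.97, 0.94)
  d <- c(1, 2, 3)
  fit <- regress(r, d)
  expect_lt(fit$slope, 0)
})
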