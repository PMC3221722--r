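make_panel <- function(seed, n = 60, n_panel = 4,
                       conds = c(
                         lapply(c(80, 100, 160, 400, 640),
                                function(ng) c(rna_input_ng = ng)),
                         lapply(c("1:150", "1:500"),
                                function(d) c(atp_dilution = d)),
                         list(c(lot_id = "B"), c(extraction_kit = "HP"),
                              c(labeling_kit = "F"))),
                       config = sim_config(seed = seed)) {
  coh <- generate_cohort(config, n)
  e <- avg_diff_raw(coh$intensities, coh$annotation)
  y <- coh$samples$recurrence
  model <- train_prognostic(e, y, inner_loocv_consensus(e, y, 30)$consensus)
  panel <- coh$samples$sample_id[seq_len(n_panel)]
  ints <- coh$intensities[, paste0(panel, "_ref"), drop = FALSE]
  sheets <- coh$samples[coh$samples$sample_id %in% panel, ]
  for (s in panel) {
    r <- generate_condition_replicates(coh, s, conds)
    ints <- cbind(ints, r$intensities)
    sheets <- rbind(sheets, r$samples)
  }
  list(model = model, intensities = ints, samples = sheets,
       annotation = coh$annotation, cohort = coh)
}

test_that("replicates identical to the reference are fully concordant", {
  p <- make_panel(1, n = 20, n_panel = 2,
                  conds = list(c(rna_input_ng = 600), c(atp_dilution = "1:50")))
  # conditions identical to the reference levels: re-rendered replicate
  # noise only, but calls must match under every null condition too
  rep <- robustness_calls(p$model, p$intensities, p$samples, p$annotation)
  expect_true(all(rep$concordance == 1))
})

test_that("the Table-5-style pattern holds: labeling flips, the rest do not", {
  p <- make_panel(2)
  rep <- robustness_calls(p$model, p$intensities, p$samples, p$annotation)
  expect_equal(unname(rep$concordance["rna_input_ng"]), 1)
  expect_equal(unname(rep$concordance["atp_dilution"]), 1)
  expect_equal(unname(rep$concordance["lot_id"]), 1)
  expect_equal(unname(rep$concordance["extraction_kit"]), 1)
  expect_lt(rep$concordance["labeling_kit"], 1)
})

test_that("removing the labeling effect restores labeling concordance", {
  p <- make_panel(2, config = sim_config(seed = 2,
                                         labeling_f_compression = 1,
                                         labeling_probe_sd = 1e-9))
  rep <- robustness_calls(p$model, p$intensities, p$samples, p$annotation)
  expect_equal(unname(rep$concordance["labeling_kit"]), 1)
})

test_that("replicates varying more than one covariate are rejected", {
  p <- make_panel(1, n = 20, n_panel = 1,
                  conds = list(c(rna_input_ng = 80)))
  bad <- p$samples
  bad$atp_dilution[bad$rna_input_ng == 80] <- "1:150"
  expect_error(robustness_calls(p$model, p$intensities, bad, p$annotation),
               "varies 2 covariates")
})

test_that("Kaplan-Meier curves match hand product-limit computations", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1), rep("g", 3))
  ev <- km[km$n_event > 0, ]
  expect_equal(ev$survival, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)

  # all censored: survival stays at 1
  km0 <- km_estimate(c(5, 6, 7), c(0, 0, 0), rep("g", 3))
  expect_true(all(km0$survival == 1))

  # doubling every subject leaves the curve unchanged
  t1 <- c(2, 4, 6, 8); e1 <- c(1, 0, 1, 1)
  a <- km_estimate(t1, e1, rep("g", 4))
  b <- km_estimate(rep(t1, 2), rep(e1, 2), rep("g", 8))
  expect_equal(a$survival[a$n_event > 0], b$survival[b$n_event > 0],
               tolerance = 1e-12)

  expect_error(km_estimate(c(-1, 2), c(1, 1), c("g", "g")), "negative")
})

test_that("without censoring the KM curve is the empirical survival function", {
  set.seed(40)
  t_ <- sort(stats::rexp(15, 0.1))
  km <- km_estimate(t_, rep(1, 15), rep("g", 15))
  ev <- km[km$n_event > 0, ]
  emp <- vapply(ev$time, function(tt) mean(t_ > tt), 1)
  expect_equal(ev$survival, emp, tolerance = 1e-12)
})

test_that("km_estimate matches the explicit product-limit oracle with censoring", {
  set.seed(41)
  for (i in 1:10) {
    n <- sample(8:20, 1)
    t_ <- round(stats::rexp(n, 0.1), 1)
    e_ <- stats::rbinom(n, 1, 0.7)
    if (sum(e_) == 0) e_[1] <- 1L
    km <- km_estimate(t_, e_, rep("g", n))
    ref <- oracle_km(t_, e_)
    ev <- km[km$n_event > 0, ]
    expect_equal(ev$time, ref$time, tolerance = 1e-12)
    expect_equal(ev$survival, ref$surv, tolerance = 1e-8)
  }
})

test_that("log-rank reproduces the hand O/E/V table and its invariances", {
  t_ <- c(1, 2, 3, 4, 5, 6)
  e_ <- c(1, 1, 1, 1, 0, 1)
  g <- c("a", "b", "a", "b", "a", "b")
  got <- logrank(t_, e_, g)
  ref <- oracle_logrank(t_, e_, g)
  expect_equal(got$chi_squared, ref$chi, tolerance = 1e-8)
  expect_equal(got$p_value, ref$p, tolerance = 1e-8)

  # label swap invariance
  swapped <- logrank(t_, e_, ifelse(g == "a", "b", "a"))
  expect_equal(swapped$chi_squared, got$chi_squared, tolerance = 1e-12)

  # identical groups: duplicated data under both labels
  same <- logrank(rep(t_, 2), rep(e_, 2), rep(c("a", "b"), each = 6))
  expect_equal(same$chi_squared, 0, tolerance = 1e-10)
  expect_equal(same$p_value, 1)

  expect_error(logrank(t_, e_, rep("a", 6)), "2 groups")
  expect_error(logrank(t_, rep(0, 6), g), "one event")
})

test_that("log-rank matches the oracle on random censored data", {
  set.seed(42)
  for (i in 1:20) {
    n <- 2 * sample(5:15, 1)
    t_ <- round(stats::rexp(n, 0.1), 1)
    e_ <- stats::rbinom(n, 1, 0.7)
    if (sum(e_) == 0) e_[1] <- 1L
    g <- rep(c("a", "b"), n / 2)
    got <- logrank(t_, e_, g)
    ref <- oracle_logrank(t_, e_, g)
    expect_equal(got$chi_squared, ref$chi, tolerance = 1e-8)
  }
})

test_that("log-rank p-values are approximately uniform under exchangeability", {
  set.seed(43)
  t_ <- stats::rexp(40, 0.05)
  e_ <- stats::rbinom(40, 1, 0.8)
  ps <- vapply(1:500, function(i) {
    logrank(t_, e_, sample(rep(c("a", "b"), 20)))$p_value
  }, 1)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.005)
})

test_that("predicted groups separate survival end-to-end", {
  set.seed(44)
  hits <- 0
  for (sd in 1:5) {
    coh <- generate_cohort(sim_config(seed = 100 + sd), 40)
    e <- avg_diff_raw(coh$intensities, coh$annotation)
    r <- nested_loocv(e, coh$samples$recurrence, k_grid = c(5, 10, 15))
    sam <- coh$samples[match(r$folds$held_out, coh$samples$array_id), ]
    if (length(unique(r$folds$call)) < 2) next
    lr <- logrank(sam$time_months, sam$event, r$folds$call)
    hits <- hits + (lr$p_value < 0.05)
  }
  expect_gte(hits, 4)
})
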