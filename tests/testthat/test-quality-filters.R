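test_that("redundancy filter reproduces the enumerated duplicate-case rates", {
  set.seed(3)
  f1 <- rnorm(30)
  # f2 = 2*f1 (|r| = 1); f3, f4 independent of everything
  m <- fm_from(f1 = f1, f2 = 2 * f1, f3 = rnorm(30), f4 = rnorm(30))
  out <- redundancy_filter(m, threshold = 0.85)
  expect_equal(nrow(out$dropped), 1L)
  expect_equal(out$redundancy_rate, 25)
  expect_true(out$dropped$feature %in% c("f1", "f2"))

  # three identical features: one survives, rate 2/3
  m3 <- fm_from(a = f1, b = f1, c = f1)
  out3 <- redundancy_filter(m3, threshold = 0.85)
  expect_equal(length(out3$retained), 1L)
  expect_equal(out3$redundancy_rate, 100 * 2 / 3, tolerance = 1e-9)

  # threshold 1: |r| > 1 impossible, nothing drops
  out1 <- redundancy_filter(m, threshold = 1)
  expect_equal(out1$redundancy_rate, 0)
  expect_equal(length(out1$retained), 4L)
})

test_that("redundancy filter keeps the higher-priority member and flags zero variance", {
  set.seed(4)
  f1 <- rnorm(25)
  m <- fm_from(low = f1, high = f1 + rnorm(25, sd = 1e-6), flat = rep(2, 25))
  out <- redundancy_filter(m, threshold = 0.85,
                           priority = c(low = 1, high = 5, flat = 3))
  expect_identical(out$retained, "high")
  expect_setequal(out$dropped$feature, c("low", "flat"))
  expect_equal(out$dropped$reason[out$dropped$feature == "flat"],
               "zero_variance")
  expect_error(redundancy_filter(m, priority = c(low = 1)),
               class = "serfe_validation_error")
  expect_error(redundancy_filter(random_fm(2, 3)),
               class = "serfe_validation_error")  # needs >= 3 patients
})

test_that("no retained pair exceeds the threshold (brute-force oracle)", {
  co <- generate_cohort(synthetic_cohort_spec(n_patients = 120, seed = 5))
  out <- redundancy_filter(co$features, threshold = 0.85)
  cm <- abs(cor(out$matrix$values))
  diag(cm) <- 0
  expect_lte(max(cm), 0.85)
  # conservation at the filter level
  expect_setequal(c(out$retained, out$dropped$feature),
                  colnames(co$features$values))
})

test_that("ICC is exact in degenerate designs and respects its invariances", {
  base <- fm_from(f = c(1, 2, 3), ids = c("S1", "S2", "S3"))
  arr <- array(rep(c(1, 2, 3), 2), dim = c(3, 1, 2),
               dimnames = list(c("S1", "S2", "S3"), "f", NULL))
  rs <- replicate_set(base, arr)
  icc <- icc_estimate(rs)
  expect_equal(icc$icc, 1)                 # identical replicates
  expect_equal(icc$sigma_w2, 0)

  # no between-subject signal: clipped to 0
  set.seed(6)
  rs0 <- simulate_icc_replicates(40, 3, sigma_b2 = 0, sigma_w2 = 1,
                                 n_features = 5, seed = 6)
  icc0 <- icc_estimate(rs0)
  expect_true(all(icc0$icc >= 0 & icc0$icc < 0.35))
  expect_true(all(icc0$sigma_b2 >= 0))

  # shift and scale invariance
  rs1 <- simulate_icc_replicates(50, 3, 2, 1, n_features = 3, seed = 7)
  icc1 <- icc_estimate(rs1)
  shifted <- replicate_set(rs1$base, rs1$replicate_values + 100)
  scaled <- replicate_set(rs1$base, rs1$replicate_values * 7)
  expect_equal(icc_estimate(shifted)$icc, icc1$icc, tolerance = 1e-9)
  expect_equal(icc_estimate(scaled)$icc, icc1$icc, tolerance = 1e-9)
})

test_that("ICC estimator agrees with one-way ANOVA mean squares from aov", {
  rs <- simulate_icc_replicates(20, 4, 3, 1, n_features = 1, seed = 8)
  y <- as.vector(rs$replicate_values[, 1, ])
  subj <- factor(rep(sprintf("S%04d", 1:20), times = 4))
  ms <- summary(aov(y ~ subj))[[1]][["Mean Sq"]]
  icc <- icc_estimate(rs)
  expect_equal(icc$ms_between, ms[1], tolerance = 1e-9)
  expect_equal(icc$ms_within, ms[2], tolerance = 1e-9)
})

test_that("ICC parameter recovery over the variance-component grid", {
  grid <- list(c(1, 1), c(3, 1), c(1, 3), c(9, 1))
  for (g in grid) {
    # 50 independent features = 50 Monte-Carlo repetitions in one call
    rs <- simulate_icc_replicates(200, 3, g[1], g[2], n_features = 50,
                                  seed = 100 + g[1] * 10 + g[2])
    est <- mean(icc_estimate(rs)$icc)
    expect_lt(abs(est - g[1] / (g[1] + g[2])), 0.03)
  }
})

test_that("stability filter scores and boundary semantics follow the ICC rule", {
  iccs <- data.frame(feature = sprintf("f%03d", 1:100),
                     icc = c(rep(0.9, 92), rep(0.5, 8)))
  out <- stability_filter(iccs, threshold = 0.75)
  expect_equal(out$stability_score, 92.0)
  expect_equal(length(out$retained), 92L)

  out0 <- stability_filter(iccs, threshold = 1e-12)
  expect_equal(out0$stability_score, 100)

  # >= is inclusive at the threshold
  b <- data.frame(feature = c("a", "b", "c"), icc = c(0.8, 0.74999, 0.75))
  outb <- stability_filter(b, threshold = 0.75)
  expect_setequal(outb$retained, c("a", "c"))
})

test_that("filter report conserves features and handles absent replicates", {
  co <- generate_cohort(synthetic_cohort_spec(seed = 9))
  res <- suppressMessages(run_serfe(co$features, config = serfe_config(seed = 9),
                                    evaluate = FALSE))
  rep_ <- res$filter_report
  expect_setequal(c(rep_$retained_features, rep_$dropped$feature),
                  colnames(co$features$values))
  expect_equal(rep_$stability_score, "not_assessed")  # no replicates given
  expect_error(
    assemble_filter_report(c("a", "b"), "a",
                           data.frame(feature = "c", reason = "redundant",
                                      statistic = 1),
                           redundancy_rate = 0),
    class = "serfe_internal_error")
})

test_that("relative redundancy reduction matches the benchmark arithmetic", {
  expect_equal(relative_redundancy_reduction(40, 10), 75)
  expect_error(relative_redundancy_reduction(0, 1),
               class = "serfe_validation_error")
})
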