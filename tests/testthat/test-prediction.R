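grid <- seq(40, 90, by = 1 / 26)

test_that("trapezoidal prediction is exact for constant and linear rates", {
  rc <- rate_curve(grid, rep(-2, length(grid)))
  expect_equal(predict_followup(100, 50, 52.3, rc), 100 - 4.6,
               tolerance = 1e-12)
  rcl <- rate_curve(grid, 0.03 * grid)
  a0 <- 51.17; a1 <- 55.93  # deliberately off-grid endpoints
  expect_equal(predict_followup(100, a0, a1, rcl),
               100 + 0.03 * (a1^2 - a0^2) / 2, tolerance = 1e-10)
  # vectorized over subjects
  expect_equal(predict_followup(c(100, 200), c(50, 60), c(52, 61), rc),
               c(96, 198), tolerance = 1e-10)
})

test_that("prediction guards its inputs", {
  rc <- rate_curve(grid, rep(-2, length(grid)))
  pc <- rate_curve(grid, rep(-2, length(grid)), units_mode = "percent")
  expect_error(predict_followup(100, 60, 58, rc), "exceed")
  expect_error(predict_followup(100, 60, 62, pc), "absolute")
  expect_error(predict_followup(100, 20, 62, rc), "clamp margin")
  # within the margin the overhang integrates at the edge rate
  expect_equal(predict_followup(100, 39.5, 40.5, rc, clamp_margin = 1),
               98, tolerance = 1e-10)
})

test_that("naive predictions are the identity with AE = |y1 - y0|", {
  cfg <- simulation_config(n_subjects = 80, seed = 5)
  co <- simulate_cohort(cfg)
  recs <- predict_cohort(co, method = "naive")
  expect_equal(recs$y1_pred, co$y0)
  expect_equal(recs$ae, abs(co$y1 - co$y0))
  expect_equal(recs$ae_norm, abs(co$y1 - co$y0) / co$y0)
})

test_that("a self-consistent cohort is predicted almost exactly", {
  # every subject sits on the median curve and moves along it
  cfg <- simulation_config(n_subjects = 3000,
                           curve = median_curve("linear", intercept = 100,
                                                slope = -0.5),
                           sigma_rel = 1e-4, nu = 1, tau = 1000,
                           slope_sd = 0, noise_sd = 0, seed = 6)
  co <- single_stratum(simulate_cohort(cfg))
  sp <- split_cohort(co, 0.5, seed = 1)
  m <- fit_centile_model(sp$train, "y0")
  recs <- predict_cohort(sp$test, m, method = "median")
  expect_lt(mean_absolute_error(recs), 0.05)
})

test_that("individual-centile predictions scale with the centile factor", {
  # subjects differ only multiplicatively; with nu = 1 the predicted change
  # for subject i is close to factor_i times the median change
  cfg <- recovery_config(n = 4000, seed = 31)
  co <- single_stratum(simulate_cohort(cfg))
  sp <- split_cohort(co, 0.5, seed = 2)
  m <- fit_centile_model(sp$train, "y0")
  test_small <- sp$test[1:120, ]
  ind <- predict_cohort(test_small, m, method = "individual")
  med <- predict_cohort(test_small, m, method = "median")
  f <- test_small$truth_centile_factor
  keep <- f > 0.9 & f < 1.1  # inside the clamp band
  ratio <- (ind$y1_pred - ind$y0)[keep] / (med$y1_pred - med$y0)[keep]
  expect_lt(median(abs(ratio / f[keep] - 1)), 0.05)
  # recovered baseline centiles track the generative factor ordering
  expect_gt(cor(ind$k[keep], f[keep], method = "spearman"), 0.95)
})

test_that("MAE and the paired comparison algebra are exact", {
  expect_equal(mean_absolute_error(make_records(c(0, 1))), 0.5)
  expect_equal(mean_absolute_error(make_records(rep(0, 5))), 0)
  expect_equal(mean_absolute_error(make_records(1:4)), 2.5)
  expect_error(mean_absolute_error(make_records(1)[0, ]), "no prediction")

  a <- make_records(c(1, 2, 3))
  cmp_same <- compare_mae(a, a)
  expect_equal(cmp_same$statistic, 0)
  expect_equal(cmp_same$p, 1)
  expect_equal(cmp_same$percent_reduction, 0)
  expect_true(is.na(cmp_same$cohens_d))

  # diffs {0, 1, 2}: d = mean/sd = 1 exactly
  b <- make_records(c(1, 1, 1))
  cmp <- compare_mae(a, b)
  expect_equal(cmp$cohens_d, 1)
  expect_equal(cmp$mean_difference, 1)
  # percent reduction recomputed from the tables, exactly
  expect_equal(cmp$percent_reduction,
               (mean(b$ae) - mean(a$ae)) / mean(b$ae) * 100)

  # diffs {-1, 0, 1}: t = 0
  cmp0 <- compare_mae(make_records(c(0, 1, 2)), make_records(c(1, 1, 1)))
  expect_equal(cmp0$statistic, 0)
})

test_that("rate comparisons detect and sign the cohort bias", {
  rc <- rate_curve(grid, rep(-0.5, length(grid)))
  rs0 <- structure(data.frame(subject_id = 1:50, sex = "F", site = "s",
                              mid_age = seq(45, 85, length.out = 50),
                              interval = 2, y0 = 100,
                              rate = -0.5, rate_percent = NA_real_),
                   class = c("rate_sample", "data.frame"))
  cmp0 <- compare_rate_estimates(rc, rs0)
  expect_equal(cmp0$statistic, 0)

  # |d| grows with the injected gap, and t carries its sign
  set.seed(17)
  noise <- rnorm(200, 0, 0.3)
  ds <- sapply(c(0.1, 0.2, 0.4), function(g) {
    rs <- rs0[rep(1, 200), ]
    rs$subject_id <- 1:200
    rs$mid_age <- seq(45, 85, length.out = 200)
    rs$rate <- -0.5 + g + noise
    cmp <- compare_rate_estimates(rc, rs)
    expect_gt(cmp$statistic, 0)
    abs(cmp$cohens_d)
  })
  expect_true(all(diff(ds) > 0))
})

test_that("the permutation null is guarded, exact when degenerate, seeded", {
  cfg <- simulation_config(n_subjects = 200, seed = 19)
  co <- simulate_cohort(cfg)
  rc <- rate_curve(seq(40, 90, by = 1 / 26),
                   rep(-1, length(seq(40, 90, by = 1 / 26))))
  expect_error(permutation_null(co, rc, n_perm = 0), "positive")
  # age-invariant predictions: every null MAE ties the observed, p = 1
  pn <- permutation_null(co, rc, n_perm = 49, seed = 3)
  expect_equal(pn$p, 1)
  expect_equal(max(abs(pn$null_mae - pn$observed_mae)), 0, tolerance = 1e-9)
  # seeded reproducibility with an age-varying curve
  rc2 <- rate_curve(seq(40, 90, by = 1 / 26),
                    -1 + 0.02 * (seq(40, 90, by = 1 / 26) - 65))
  a <- permutation_null(co, rc2, n_perm = 30, seed = 4)
  b <- permutation_null(co, rc2, n_perm = 30, seed = 4)
  expect_identical(a$null_mae, b$null_mae)
  expect_identical(a$p, b$p)
})

test_that("permutation p-values are valid in the rejection range", {
  # age-independent true rates; an age-tilted prediction curve centred on
  # the cohort: spurious significance must stay at or below nominal
  set.seed(23)
  gridw <- seq(40, 92, by = 1 / 26)
  rc <- rate_curve(gridw, -2 + 0.05 * (gridw - 64.5))
  ps <- replicate(120, {
    n <- 60
    a0 <- runif(n, 47, 80)
    co <- data.frame(subject_id = 1:n, sex = "F", site = "s",
                     age0 = a0, age1 = a0 + 2,
                     y0 = 100 + rnorm(n), y1 = NA_real_)
    co$y1 <- co$y0 - 4 + rnorm(n, 0, 1.5)
    permutation_null(co, rc, n_perm = 49, seed = sample.int(1e6, 1))$p
  })
  for (alpha in c(0.05, 0.1, 0.2)) {
    se <- sqrt(alpha * (1 - alpha) / length(ps))
    expect_lte(mean(ps <= alpha), alpha + 2 * se)
  }
})

test_that("upward fractions count strictly positive rates", {
  rs <- structure(data.frame(rate = c(-1, 2, 3, -4)),
                  class = c("rate_sample", "data.frame"))
  expect_equal(upward_fraction(rs), 0.5)
  expect_equal(upward_fraction(data.frame(rate = c(-1, -2))), 0)
  expect_equal(upward_fraction(data.frame(rate = c(0, 1))), 0.5)

  # closed-form oracle at n = 20,000
  cfg <- simulation_config(n_subjects = 20000,
                           curve = median_curve("linear", intercept = 150,
                                                slope = -0.5),
                           sigma_rel = 0, slope_sd = 0.4, noise_sd = 0.3,
                           interval_mean = 2, interval_sd = 0, seed = 20)
  co <- simulate_cohort(cfg)
  frac <- upward_fraction(annualized_rates(co))
  want <- expected_upward_fraction(cfg, 60)
  se <- sqrt(want * (1 - want) / 20000)
  expect_lt(abs(frac - want), 3 * se)
})

test_that("BH adjustment matches the hand rule and the brute-force oracle", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.37), 0.37)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
  expect_error(fdr_adjust(c(0.5, NA)), "0, 1")
  set.seed(24)
  for (i in 1:200) {
    p <- runif(sample(1:20, 1))
    adj <- fdr_adjust(p)
    expect_equal(adj, bh_oracle(p))
    expect_true(all(adj >= p - 1e-15))
  }
})
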