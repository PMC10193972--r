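# canonical parameter-recovery fit, reused across several blocks
co_rec <- single_stratum(simulate_cohort(recovery_config()))
model_rec <- fit_centile_model(co_rec, "y0")

test_that("the fitted median recovers the generative location curve", {
  fit <- model_rec$strata[[1]]
  expect_true(fit$converged)
  # central 90% of the age range
  ages <- seq(47 + 0.05 * 33, 80 - 0.05 * 33, length.out = 60)
  med <- evaluate_centile(model_rec, 0.5, ages)
  expect_lt(max(abs(med$value / (100 - 0.5 * ages) - 1)), 0.01)
  # shape parameters land near the generative ones
  expect_lt(abs(fit$nu - 1), 1)
  expect_gt(fit$tau, 3)
})

test_that("an upper centile matches the generative 84th percentile", {
  q84_true <- qbct(0.84, 100 - 0.5 * 60, 0.05, 1, 10)
  q84_fit <- evaluate_centile(model_rec, 0.84, 60)$value
  expect_lt(abs(q84_fit / q84_true - 1), 0.015)
})

test_that("refitting the same table is deterministic", {
  m2 <- fit_centile_model(co_rec, "y0")
  expect_identical(model_rec$strata[[1]]$beta_mu, m2$strata[[1]]$beta_mu)
  expect_identical(model_rec$strata[[1]]$nu, m2$strata[[1]]$nu)
  expect_identical(model_rec$strata[[1]]$tau, m2$strata[[1]]$tau)
})

test_that("centile curves never cross in k", {
  ages <- seq(48, 79, length.out = 40)
  ks <- c(0.02, 0.16, 0.5, 0.84, 0.98)
  vals <- sapply(ks, function(k)
    evaluate_centile(model_rec, k, ages)$value)
  expect_true(all(apply(vals, 1, diff) > 0))
})

test_that("near-constant data yield a flat location fit", {
  set.seed(4)
  n <- 200
  co <- data.frame(subject_id = 1:n, sex = "F", site = "s1",
                   age0 = runif(n, 50, 78),
                   y0 = 100 + rnorm(n, 0, 0.01))
  co$age1 <- co$age0 + 2
  co$y1 <- co$y0
  m <- fit_centile_model(co, "y0")
  med <- evaluate_centile(m, 0.5, seq(50.5, 77.5, by = 1))$value
  expect_lt(max(abs(med - 100)), 0.05)
  # centile spread shrinks toward the jitter scale
  spread <- evaluate_centile(m, 0.84, 64)$value -
    evaluate_centile(m, 0.16, 64)$value
  expect_lt(spread, 0.1)
})

test_that("age-domain rules and stratum lookup are enforced", {
  expect_error(evaluate_centile(model_rec, 0.5, c(40, 60)), "age domain")
  clamped <- evaluate_centile(model_rec, 0.5, c(40, 60), rule = "clamp")
  at_edge <- evaluate_centile(model_rec, 0.5,
                              model_rec$strata[[1]]$age_domain[1])
  expect_equal(clamped$value[1], at_edge$value)
  expect_error(evaluate_centile(model_rec, 0.5, 60, stratum = "nope"),
               "unknown stratum")
  expect_error(evaluate_centile(model_rec, 1.5, 60), "in \\(0, 1\\)")
})

test_that("small strata are skipped with a warning", {
  co <- co_rec
  co$site[1:10] <- "tiny"
  expect_warning(m <- fit_centile_model(co, "y0"), "skipped")
  expect_named(m$strata, "F.site1")
})

test_that("baseline percentiles invert the centile curves", {
  med60 <- evaluate_centile(model_rec, 0.5, 60)$value
  # the fitted median scores 0.5
  expect_equal(baseline_percentile(model_rec, med60, 60), 0.5,
               tolerance = 1e-9)
  # round trip inside the clamp band
  for (k in c(0.05, 0.3, 0.9)) {
    y <- evaluate_centile(model_rec, k, 63)$value
    expect_equal(baseline_percentile(model_rec, y, 63), k, tolerance = 1e-8)
    expect_equal(evaluate_centile(model_rec,
                                  baseline_percentile(model_rec, y, 63),
                                  63)$value, y, tolerance = 1e-6)
  }
  # extreme values clamp
  expect_equal(baseline_percentile(model_rec, 500, 60), 0.99)
  expect_equal(baseline_percentile(model_rec, 1e-3, 60), 0.01)
})

test_that("quantile residuals are standard normal under the fitted model", {
  fit <- model_rec$strata[[1]]
  # simulate fresh data from the fitted model itself
  set.seed(8)
  n <- 4000
  ages <- runif(n, 47, 80)
  pa <- chartrates:::params_at_age(fit, ages)
  co <- data.frame(subject_id = 1:n, sex = "F", site = "site1",
                   age0 = ages, age1 = ages + 2,
                   y0 = qbct(runif(n), pa$mu, pa$sigma, pa$nu, pa$tau))
  co$y1 <- co$y0
  zr <- z_residuals(model_rec, co)
  sm <- attr(zr, "summary")
  expect_lt(abs(sm$mean), 3 / sqrt(n))
  expect_lt(abs(sm$sd^2 - 1), 3 * sqrt(2 / n))
  # a single observation at the fitted median scores residual zero
  med <- evaluate_centile(model_rec, 0.5, 60)$value
  one <- co[1, ]; one$age0 <- 60; one$y0 <- med
  expect_equal(z_residuals(model_rec, one)$z, 0, tolerance = 1e-6)
})

test_that("heavy-tailed contamination inflates residual kurtosis", {
  set.seed(9)
  co <- co_rec
  idx <- sample(nrow(co), nrow(co) %/% 10)
  co$y0[idx] <- co$y0[idx] * 1.5
  zr <- z_residuals(model_rec, co)
  expect_gt(attr(zr, "summary")$excess_kurtosis, 0)
})

test_that("model serialization round-trips through JSON", {
  path <- tempfile(fileext = ".json")
  write_centile_model(model_rec, path)
  m2 <- read_centile_model(path)
  expect_equal(m2$strata[[1]]$beta_mu, model_rec$strata[[1]]$beta_mu)
  expect_equal(m2$strata[[1]]$tau, model_rec$strata[[1]]$tau)
  ages <- seq(50, 75, length.out = 7)
  expect_equal(evaluate_centile(m2, 0.84, ages)$value,
               evaluate_centile(model_rec, 0.84, ages)$value)
  suppressWarnings(expect_error(read_centile_model(tempfile()),
                                "cannot open|No such"))
  unlink(path)
})

test_that("bootstrap bands are seeded and degenerate correctly", {
  # forced degeneracy: every subject identical, so any resample with
  # replacement reproduces the same table and bands collapse onto the
  # point estimate
  co_same <- data.frame(subject_id = 1:60, sex = "F", site = "s1",
                        age0 = 60, age1 = 62, y0 = 100, y1 = 99)
  bb <- suppressWarnings(bootstrap_bands(co_same, ages = 60, B = 3,
                                         seed = 2))
  expect_equal(bb$lower, bb$estimate)
  expect_equal(bb$upper, bb$estimate)

  # seeded reproducibility on a real cohort
  co <- single_stratum(simulate_cohort(recovery_config(n = 400, seed = 5)))
  ages <- seq(55, 72, length.out = 5)
  b1 <- bootstrap_bands(co, ages = ages, B = 8, seed = 3)
  b2 <- bootstrap_bands(co, ages = ages, B = 8, seed = 3)
  expect_identical(b1$lower, b2$lower)
  expect_identical(b1$upper, b2$upper)
  expect_true(all(b1$upper >= b1$lower))
})

test_that("bands widen when the cohort shrinks", {
  ages <- seq(55, 72, length.out = 5)
  big <- single_stratum(simulate_cohort(recovery_config(n = 1000, seed = 6)))
  small <- single_stratum(simulate_cohort(recovery_config(n = 150, seed = 6)))
  bb_big <- bootstrap_bands(big, ages = ages, B = 12, seed = 4)
  bb_small <- bootstrap_bands(small, ages = ages, B = 12, seed = 4)
  expect_gt(mean(bb_small$upper - bb_small$lower),
            mean(bb_big$upper - bb_big$lower))
})
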