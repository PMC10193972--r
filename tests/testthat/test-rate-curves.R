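h <- 1 / 26

test_that("rate-curve construction validates its grid", {
  expect_error(rate_curve(c(1, 2, 2.5), rep(0, 3)), "uniform")
  expect_error(rate_curve(c(2, 1, 0), rep(0, 3)), "uniform")
  rc <- rate_curve(seq(0, 1, by = 0.1), rep(1, 11))
  expect_s3_class(rc, "rate_curve")
})

test_that("differentiation reproduces the printed percent-rate formula", {
  grid <- seq(47, 80, by = h)

  # constant curve: zero everywhere
  flat <- structure(data.frame(age = grid, value = rep(100, length(grid))),
                    class = c("centile_curve", "data.frame"))
  expect_equal(differentiate_centile(flat, "absolute")$rate,
               rep(0, length(grid) - 1))

  # linear curve y = 100 - 0.5 a: absolute rate exactly -0.5; percent rate
  # at the midpoint of (60, 60 + h) is -0.5 * 100 / y(60)
  lin <- structure(data.frame(age = grid, value = 100 - 0.5 * grid),
                   class = c("centile_curve", "data.frame"))
  ra <- differentiate_centile(lin, "absolute")
  expect_equal(ra$rate, rep(-0.5, length(grid) - 1), tolerance = 1e-10)
  rp <- differentiate_centile(lin, "percent")
  i60 <- which(abs(grid - 60) < 1e-9)
  expect_equal(rp$age[i60], 60 + h / 2)
  expect_equal(rp$rate[i60], -0.5 * 100 / (100 - 0.5 * 60),
               tolerance = 1e-10)

  # exponential decline: percent rate is -1 %/yr + O(h) at every age
  ex <- structure(data.frame(age = grid, value = 100 * exp(-0.01 * grid)),
                  class = c("centile_curve", "data.frame"))
  rpe <- differentiate_centile(ex, "percent")
  expect_equal(rpe$rate, rep(-1, length(rpe$rate)), tolerance = 2 * h)

  # guards
  bad <- data.frame(age = c(1, 2, 4), value = c(1, 1, 1))
  expect_error(differentiate_centile(bad), "uniform")
  neg <- data.frame(age = grid, value = rep(-1, length(grid)))
  expect_error(differentiate_centile(neg), "positive")
})

test_that("boxcar smoothing has the exact window algebra", {
  grid <- seq(50, 70, by = h)
  n <- length(grid)

  # linear rate curves are invariant on interior symmetric windows
  lin <- rate_curve(grid, 2 * grid - 100)
  sm <- smooth_rate(lin, 2.5)
  interior <- grid >= 50 + 2.5 & grid <= 70 - 2.5
  expect_equal(sm$rate[interior], lin$rate[interior], tolerance = 1e-10)
  expect_true(attr(sm, "smoothed"))

  # constants are unchanged everywhere, including truncated boundaries
  cst <- rate_curve(grid, rep(3, n))
  expect_equal(smooth_rate(cst, 2.5)$rate, rep(3, n))

  # a unit spike spreads to 1/w over its covering windows
  spike <- rep(0, n); mid <- n %/% 2; spike[mid] <- 1
  w <- 2 * floor(2.5 / h + 1e-9) + 1
  smsp <- smooth_rate(rate_curve(grid, spike), 2.5)
  expect_equal(smsp$rate[mid], 1 / w, tolerance = 1e-12)
  # direct convolution oracle over the full interior
  conv <- stats::filter(spike, rep(1 / w, w), sides = 2)
  inner <- (w %/% 2 + 1):(n - w %/% 2)
  expect_equal(smsp$rate[inner], as.numeric(conv[inner]), tolerance = 1e-12)

  # span below grid spacing: identity with warning
  expect_warning(same <- smooth_rate(lin, h / 10), "span")
  expect_equal(same$rate, lin$rate)
})

test_that("annualized rates follow their definition", {
  co <- data.frame(subject_id = 1:2, sex = "F", site = "s",
                   age0 = c(60, 70), age1 = c(62, 71.5),
                   y0 = c(100, 50), y1 = c(98, 50))
  rs <- annualized_rates(co)
  expect_equal(rs$rate, c(-1, 0))
  expect_equal(rs$rate_percent, c(-1, 0))
  expect_equal(rs$mid_age, c(61, 70.75))

  # generator oracle: noise-free slope -2 everywhere
  cfg <- simulation_config(n_subjects = 50,
                           curve = median_curve("linear", intercept = 200,
                                                slope = -2),
                           sigma_rel = 0, slope_sd = 0, noise_sd = 0,
                           seed = 3)
  rs2 <- annualized_rates(simulate_cohort(cfg))
  expect_equal(rs2$rate, rep(-2, 50), tolerance = 1e-10)
})

test_that("the rate chart recovers constant and sloping rate structure", {
  set.seed(10)
  n <- 400
  mid <- runif(n, 50, 78)
  rs <- structure(data.frame(subject_id = 1:n, sex = "F", site = "s",
                             mid_age = mid, interval = 2, y0 = 100,
                             rate = -0.5 + rnorm(n, 0, 0.01),
                             rate_percent = NA_real_),
                  class = c("rate_sample", "data.frame"))
  ch <- suppressWarnings(fit_rate_chart(rs))  # near-zero scale: benign gam warnings
  med <- evaluate_rate_chart(ch, seq(52, 76, by = 1))
  expect_lt(max(abs(med$rate + 0.5)), 0.02)
  expect_identical(attr(med, "provenance"), "longitudinal")

  # deterministic refit
  ch2 <- suppressWarnings(fit_rate_chart(rs))
  expect_identical(evaluate_rate_chart(ch2, c(55, 65))$rate,
                   evaluate_rate_chart(ch, c(55, 65))$rate)
  # small strata are skipped (the near-degenerate scale fit may also warn)
  rs_small <- rs; rs_small$site <- rep(c("s", "tiny"), c(n - 10, 10))
  w <- capture_warnings(fit_rate_chart(rs_small))
  expect_true(any(grepl("skipped", w)))
})

test_that("the rate chart recovers a sloping generative derivative", {
  cur <- median_curve("quadratic", ref = 47, value = 100, slope = -0.1,
                      curvature = -0.02)
  cfg <- simulation_config(n_subjects = 10000, curve = cur, sigma_rel = 0.02,
                           nu = 1, tau = 1000, slope_sd = 0, noise_sd = 0.3,
                           seed = 11)
  co <- single_stratum(simulate_cohort(cfg))
  ch <- fit_rate_chart(annualized_rates(co))
  ages <- seq(51, 76, by = 0.5)
  med <- evaluate_rate_chart(ch, ages)
  expect_lt(max(abs(med$rate / cur$mprime(ages) - 1)), 0.10)
})

test_that("percent difference follows its magnitude convention", {
  grid <- seq(50, 70, by = h)
  a <- rate_curve(grid, rep(-0.5, length(grid)))
  b <- rate_curve(grid, rep(-1, length(grid)))
  # identical curves: zero everywhere
  pd0 <- percent_difference(a, a)
  expect_true(all(abs(pd0$curve$percent_difference) < 1e-12))
  # cross half the longitudinal magnitude: 50% underestimation
  pd <- percent_difference(a, b)
  expect_equal(pd$max_percent_difference, 50)
  expect_true(all(pd$curve$percent_difference == 50))
  # near-zero longitudinal rates are masked
  z <- rate_curve(grid, rep(0, length(grid)))
  pdz <- percent_difference(a, z)
  expect_equal(length(pdz$masked_ages), length(grid))
  expect_error(percent_difference(a, rate_curve(grid + 100,
                                                rep(-1, length(grid)))),
               "overlap")
})

test_that("integrating the unsmoothed derivative reconstructs the centile", {
  # quadratic centile curve: midpoint sampling makes the trapezoid exact
  grid <- seq(47, 80, by = h)
  v <- 100 - 0.1 * (grid - 47) - 0.01 * (grid - 47)^2
  cc <- structure(data.frame(age = grid, value = v),
                  class = c("centile_curve", "data.frame"))
  rc <- differentiate_centile(cc, "absolute")
  i0 <- 30L; i1 <- 700L
  recon <- v[i0] + chartrates:::rate_integral(rc, grid[i0], grid[i1])
  expect_equal(recon, v[i1], tolerance = 1e-8 * abs(v[i1]))

  # and on a fitted model's median curve the error is O(h^2)
  m_loc <- fit_centile_model(
    single_stratum(simulate_cohort(recovery_config(n = 2000, seed = 21))),
    "y0")
  med <- evaluate_centile(m_loc, 0.5, seq(48, 79, by = h))
  rr <- differentiate_centile(med, "absolute")
  rec2 <- med$value[1] + chartrates:::rate_integral(rr, med$age[1],
                                                    med$age[500])
  expect_equal(rec2, med$value[500], tolerance = 1e-6)
})

test_that("cross and longitudinal median rate curves agree in the core", {
  # no cohort effect, no slope heterogeneity: the chart derivative and the
  # longitudinal rate chart estimate the same function; agreement is
  # checked away from the spline/smoother boundary region, where edge bias
  # of the penalized fit dominates
  cfg <- simulation_config(n_subjects = 10000, slope_sd = 0,
                           cohort_effect = 0, seed = 9)
  co <- single_stratum(simulate_cohort(cfg))
  m <- fit_centile_model(co, "y0")
  dom <- m$strata[[1]]$age_domain
  grid <- seq(dom[1], dom[2], by = h)
  cc <- evaluate_centile(m, 0.5, grid)
  cross <- smooth_rate(differentiate_centile(cc, "absolute"), 2.5)
  lng <- evaluate_rate_chart(fit_rate_chart(annualized_rates(co)),
                             cross$age)
  rel <- abs(cross$rate / lng$rate - 1)
  interior <- cross$age > dom[1] + 2.5 & cross$age < dom[2] - 2.5
  core <- cross$age > dom[1] + 5 & cross$age < dom[2] - 5
  expect_lt(mean(rel[interior]), 0.05)
  expect_lt(max(rel[core]), 0.10)
})

test_that("GLM and LME slopes agree without repeated-measure structure", {
  cfg <- simulation_config(n_subjects = 400,
                           curve = median_curve("linear", intercept = 100,
                                                slope = -0.5),
                           sigma_rel = 0, slope_sd = 0, noise_sd = 0,
                           cohort_effect = 0, age_range = c(40, 60),
                           seed = 14)
  co <- single_stratum(simulate_cohort(cfg))
  # zero residual variance makes the mixed fit degenerate but exact
  res <- suppressWarnings(suppressMessages(lme_vs_glm_rates(co)))
  expect_equal(res$glm_slope, -0.5, tolerance = 1e-6)
  expect_equal(res$lme_slope, -0.5, tolerance = 1e-4)
})

test_that("a birth-cohort effect separates GLM and LME slopes", {
  cfg <- simulation_config(n_subjects = 10000,
                           curve = median_curve("linear", intercept = 130,
                                                slope = -0.5),
                           sigma_rel = 0, intercept_sd = 3, slope_sd = 0,
                           noise_sd = 0.5, cohort_effect = 0.2, seed = 15)
  co <- single_stratum(simulate_cohort(cfg))
  res <- lme_vs_glm_rates(co)
  expect_equal(res$glm_slope, -0.7, tolerance = 0.02)
  # LME lies strictly between the biased cross-sectional slope and the
  # within-person slope
  expect_gt(res$lme_slope, res$glm_slope)
  expect_lt(res$lme_slope, -0.5)

  # duplicating every subject leaves both estimates unchanged
  co2 <- rbind(co, co)
  co2$subject_id <- seq_len(nrow(co2))
  res2 <- lme_vs_glm_rates(co2)
  expect_equal(res2$glm_slope, res$glm_slope, tolerance = 1e-8)
  expect_equal(res2$lme_slope, res$lme_slope, tolerance = 1e-4)
})
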