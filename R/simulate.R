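#' Population median-trajectory families
#'
#' Smooth population age trends \eqn{m(age)} with analytic derivatives,
#' used as the generative median curve of synthetic cohorts and as the
#' ground truth behind the pipeline's closed-form oracles.
#'
#' Families: \code{"linear"} (\code{intercept + slope * age});
#' \code{"quadratic"}, parameterized around a reference age as
#' \code{value + slope * (age - ref) + curvature/2 * (age - ref)^2}; and
#' \code{"logistic_decline"}, a sigmoidal fall
#' \code{floor + drop * plogis(-(age - midpoint) / scale)} emulating
#' accelerating-then-saturating atrophy.
#'
#' @param family curve family.
#' @param intercept,slope linear-family parameters (phenotype units and
#'   units/year).
#' @param ref,value,curvature quadratic-family parameters (\code{slope} is
#'   the derivative at \code{ref}; \code{curvature} is units/year^2).
#' @param floor,drop,midpoint,scale logistic-decline parameters (units,
#'   units, years, years).
#' @return an object of class \code{median_curve}: list with elements
#'   \code{m(age)}, \code{mprime(age)}, \code{family}, \code{params}.
#' @export
median_curve <- function(family = c("linear", "quadratic", "logistic_decline"),
                         intercept = 100, slope = -0.5,
                         ref = 60, value = 100, curvature = -0.02,
                         floor = 60, drop = 50, midpoint = 65, scale = 12) {
  family <- match.arg(family)
  obj <- switch(family,
    linear = list(
      m = function(a) intercept + slope * a,
      mprime = function(a) rep_len(slope, length(a)),
      params = list(intercept = intercept, slope = slope)),
    quadratic = list(
      m = function(a) value + slope * (a - ref) + curvature / 2 * (a - ref)^2,
      mprime = function(a) slope + curvature * (a - ref),
      params = list(ref = ref, value = value, slope = slope,
                    curvature = curvature)),
    logistic_decline = list(
      m = function(a) floor + drop * stats::plogis(-(a - midpoint) / scale),
      mprime = function(a) {
        p <- stats::plogis(-(a - midpoint) / scale)
        -(drop / scale) * p * (1 - p)
      },
      params = list(floor = floor, drop = drop, midpoint = midpoint,
                    scale = scale)))
  structure(c(obj, list(family = family)), class = "median_curve")
}

#' Generative configuration for synthetic longitudinal cohorts
#'
#' Full ground truth for a two-occasion cohort: a smooth population median
#' curve, cross-sectional BCT dispersion, between-person intercept and slope
#' heterogeneity, a birth-cohort (generational) effect, occasion-level
#' measurement noise, sex/site strata, and optional follow-up selection.
#' Because the study year is fixed, birth year and baseline age are
#' perfectly confounded cross-sectionally, which is exactly the mechanism
#' that biases cross-sectional charts.
#'
#' @param n_subjects number of subjects.
#' @param age_range baseline-age range (years), sampled uniformly.
#' @param interval_mean,interval_sd interscan-interval distribution (years);
#'   draws are truncated at 0.25 y.
#' @param curve a \code{\link{median_curve}}.
#' @param sigma_rel relative scale of the multiplicative BCT centile factor
#'   (0 disables); \code{nu}, \code{tau} the BCT shape parameters.
#' @param slope_sd between-person slope-deviation SD (units/year).
#' @param intercept_sd between-person additive intercept SD (units).
#' @param cohort_effect g, units per birth-year: later-born subjects differ
#'   systematically by \code{g * (birth_year - reference birth-year)}.
#' @param noise_sd additive measurement-noise SD per occasion (units).
#' @param n_sites,sex_ratio stratum structure (fraction female).
#' @param selection_beta logistic coefficient of follow-up retention on the
#'   standardized baseline deviation (0 disables selection).
#' @param study_year fixed calendar year of the baseline visit.
#' @param seed integer seed.
#' @return an object of class \code{simulation_config}.
#' @export
simulation_config <- function(n_subjects = 1000L, age_range = c(47, 80),
                              interval_mean = 2.25, interval_sd = 0.5,
                              curve = median_curve("logistic_decline"),
                              sigma_rel = 0.05, nu = 1, tau = 10,
                              slope_sd = 0.3, intercept_sd = 0,
                              cohort_effect = 0, noise_sd = 0.5,
                              n_sites = 1L, sex_ratio = 0.5,
                              selection_beta = 0, study_year = 2020,
                              seed = 1L) {
  stopifnot(n_subjects >= 1, interval_mean > 0, noise_sd >= 0, slope_sd >= 0,
            intercept_sd >= 0, sigma_rel >= 0, n_sites >= 1,
            sex_ratio >= 0, sex_ratio <= 1, age_range[2] > age_range[1],
            inherits(curve, "median_curve"))
  structure(list(n_subjects = as.integer(n_subjects), age_range = age_range,
                 interval_mean = interval_mean, interval_sd = interval_sd,
                 curve = curve, sigma_rel = sigma_rel, nu = nu, tau = tau,
                 slope_sd = slope_sd, intercept_sd = intercept_sd,
                 cohort_effect = cohort_effect, noise_sd = noise_sd,
                 n_sites = as.integer(n_sites), sex_ratio = sex_ratio,
                 selection_beta = selection_beta, study_year = study_year,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# reference birth-year: fixed at study_year - mean(age_range) so the
# generative mean function is analytic and sample-independent
ref_birth_year <- function(config) config$study_year - mean(config$age_range)

# cross-sectional population mean at baseline age a (multiplicative BCT
# factor has median ~1 and drops out of the location)
cross_mean_fun <- function(config) {
  g <- config$cohort_effect
  mid <- mean(config$age_range)
  function(a) config$curve$m(a) + g * (mid - a)
}

#' Simulate a two-occasion longitudinal cohort
#'
#' Each subject receives a uniform baseline age, a truncated-normal
#' interscan interval, a normal intercept deviation \code{u}, a normal
#' slope deviation \code{s}, and a birth year \code{study_year - age0}. The
#' noise-free value at age \code{a} is
#' \code{m(a) + u + s * (a - age0) + g * (birth_year - reference)};
#' observed values multiply this by a subject-level BCT centile factor
#' (drawn once, at baseline, and persisting to follow-up, so the baseline
#' cross-section is exactly BCT-distributed) and add independent Gaussian
#' measurement noise at each occasion. Subjects drawn non-positive are
#' re-drawn up to 100 times and counted; persistent failure aborts with a
#' description of the offending configuration. With nonzero
#' \code{selection_beta}, follow-up retention is Bernoulli with probability
#' \code{plogis(selection_beta * standardized baseline deviation)}; dropped
#' subjects are flagged in the \code{retained} column, never deleted.
#' Deterministic given the config seed.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return a \code{\link{as_longitudinal_cohort}} table with truth columns
#'   \code{truth_intercept}, \code{truth_slope} (slope deviation),
#'   \code{truth_birth_year}, \code{truth_centile_factor}, and attribute
#'   \code{n_resampled}.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  m <- config$curve$m
  g <- config$cohort_effect

  age0 <- stats::runif(n, config$age_range[1], config$age_range[2])
  interval <- stats::rnorm(n, config$interval_mean, config$interval_sd)
  for (tries in 1:100) {
    bad <- interval <= 0.25
    if (!any(bad)) break
    interval[bad] <- stats::rnorm(sum(bad), config$interval_mean,
                                  config$interval_sd)
  }
  interval <- pmax(interval, 0.25)
  age1 <- age0 + interval
  sex <- ifelse(stats::runif(n) < config$sex_ratio, "F", "M")
  site <- paste0("site", sample.int(config$n_sites, n, replace = TRUE))
  birth_year <- config$study_year - age0
  cohort_shift <- g * (birth_year - ref_birth_year(config))

  draw_subject <- function(idx) {
    k <- length(idx)
    u <- stats::rnorm(k, 0, config$intercept_sd)
    s <- stats::rnorm(k, 0, config$slope_sd)
    f <- if (config$sigma_rel > 0)
      qbct(stats::runif(k), 1, config$sigma_rel, config$nu, config$tau)
    else rep(1, k)
    e0 <- stats::rnorm(k, 0, config$noise_sd)
    e1 <- stats::rnorm(k, 0, config$noise_sd)
    t0 <- m(age0[idx]) + u + cohort_shift[idx]
    t1 <- m(age1[idx]) + u + s * interval[idx] + cohort_shift[idx]
    list(u = u, s = s, f = f, y0 = t0 * f + e0, y1 = t1 * f + e1)
  }

  d <- draw_subject(seq_len(n))
  u <- d$u; s <- d$s; f <- d$f; y0 <- d$y0; y1 <- d$y1
  n_resampled <- 0L
  for (attempt in 1:100) {
    bad <- which(y0 <= 0 | y1 <= 0)
    if (!length(bad)) break
    n_resampled <- n_resampled + length(bad)
    d <- draw_subject(bad)
    u[bad] <- d$u; s[bad] <- d$s; f[bad] <- d$f
    y0[bad] <- d$y0; y1[bad] <- d$y1
  }
  if (any(y0 <= 0 | y1 <= 0))
    stop("could not draw positive phenotype values after 100 attempts; ",
         "the configured median curve / noise scales place substantial ",
         "mass at or below zero")

  retained <- rep(TRUE, n)
  if (config$selection_beta != 0) {
    dev <- (y0 - mean(y0)) / stats::sd(y0)
    retained <- stats::runif(n) < stats::plogis(config$selection_beta * dev)
  }

  out <- data.frame(subject_id = seq_len(n), sex = sex, site = site,
                    age0 = age0, age1 = age1, y0 = y0, y1 = y1,
                    retained = retained,
                    truth_intercept = u, truth_slope = s,
                    truth_birth_year = birth_year,
                    truth_centile_factor = f)
  out <- as_longitudinal_cohort(out)
  attr(out, "n_resampled") <- n_resampled
  out
}

#' Analytic cross-sectional and longitudinal rate curves
#'
#' Closed-form oracles for the generative model: the expected within-person
#' (longitudinal) rate is \eqn{m'(age)}, while the cross-sectional age
#' gradient is \eqn{m'(age) - g} because age and birth year are perfectly
#' confounded in a single-visit snapshot. Percent-mode curves divide by the
#' cross-sectional population mean at each age and multiply by 100.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param ages age grid (years).
#' @param units \code{"absolute"} (units/year) or \code{"percent"} (\%/year).
#' @return list with \code{cross} and \code{long}, both
#'   \code{\link{rate_curve}} objects with provenance \code{"analytic"}.
#' @export
analytic_rates <- function(config, ages, units = c("absolute", "percent")) {
  stopifnot(inherits(config, "simulation_config"))
  units <- match.arg(units)
  mp <- config$curve$mprime(ages)
  cross <- mp - config$cohort_effect
  long <- mp
  if (units == "percent") {
    mu_c <- cross_mean_fun(config)(ages)
    cross <- cross / mu_c * 100
    long <- long / mu_c * 100
  }
  list(cross = rate_curve(ages, cross, units_mode = units, k = 0.5,
                          provenance = "analytic"),
       long = rate_curve(ages, long, units_mode = units, k = 0.5,
                         provenance = "analytic"))
}

#' Expected fraction of upward observed slopes
#'
#' Closed form for the probability that a subject's observed annualized
#' rate is positive at a given age:
#' \deqn{P = \Phi\!\left(\frac{m'(age)}
#'   {\sqrt{slope\_sd^2 + 2\, noise\_sd^2 / interval\_mean^2}}\right),}
#' since the observed rate is the true rate \eqn{m' + s} plus the noise
#' difference over the interval. When the denominator is zero the rate is
#' deterministic: returns 0, 1, or (by the symmetry convention) 0.5 when
#' \eqn{m' = 0}.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param age age(s) at which to evaluate (years).
#' @return probability vector.
#' @export
expected_upward_fraction <- function(config, age) {
  stopifnot(inherits(config, "simulation_config"))
  mp <- config$curve$mprime(age)
  denom <- sqrt(config$slope_sd^2 +
                  2 * config$noise_sd^2 / config$interval_mean^2)
  if (denom == 0) return(ifelse(mp > 0, 1, ifelse(mp < 0, 0, 0.5)))
  stats::pnorm(mp / denom)
}
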