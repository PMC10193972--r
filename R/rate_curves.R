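#' Rate-of-change curves on a uniform age grid
#'
#' Container for a rate-of-change function over age: a strictly increasing,
#' uniformly spaced age grid (default spacing about two weeks) with one
#' rate value per grid age, flagged as percent-of-centile-per-year or
#' absolute-units-per-year, and carrying its percentile and provenance
#' (cross-sectional chart derivative, longitudinal chart, or analytic
#' ground truth).
#'
#' @param ages uniformly spaced, strictly increasing age grid (years).
#' @param values rate at each grid age.
#' @param units_mode \code{"absolute"} (units/year) or \code{"percent"}
#'   (\%/year).
#' @param k percentile the curve belongs to.
#' @param provenance \code{"cross"}, \code{"longitudinal"} or
#'   \code{"analytic"}.
#' @param smoothed has a moving-average filter been applied.
#' @param span smoothing half-window (years), \code{NA} if unsmoothed.
#' @param ref_values source centile-curve values at the left grid endpoints,
#'   kept so percent and absolute modes stay interconvertible.
#' @return data frame (age, rate) of class \code{rate_curve}.
#' @export
rate_curve <- function(ages, values, units_mode = c("absolute", "percent"),
                       k = 0.5, provenance = c("cross", "longitudinal",
                                               "analytic"),
                       smoothed = FALSE, span = NA_real_, ref_values = NULL) {
  units_mode <- match.arg(units_mode)
  provenance <- match.arg(provenance)
  stopifnot(length(ages) == length(values), length(ages) >= 2)
  h <- diff(ages)
  if (any(h <= 0) || diff(range(h)) > 1e-9)
    stop("rate-curve age grid must be strictly increasing and uniform")
  structure(data.frame(age = ages, rate = values),
            units_mode = units_mode, k = k, provenance = provenance,
            smoothed = smoothed, span = span, ref_values = ref_values,
            class = c("rate_curve", "data.frame"))
}

#' @export
print.rate_curve <- function(x, ...) {
  cat(sprintf("rate curve (%s, k=%.2f, %s%s): %d grid ages in [%.2f, %.2f]\n",
              attr(x, "units_mode"), attr(x, "k"), attr(x, "provenance"),
              if (isTRUE(attr(x, "smoothed")))
                sprintf(", smoothed ±%.1f y", attr(x, "span")) else "",
              nrow(x), min(x$age), max(x$age)))
  invisible(x)
}

#' Differentiate a centile curve into a rate-of-change chart
#'
#' First differences of a fitted percentile curve over a uniform age grid.
#' For successive grid ages the rate at the midpoint age is
#' \deqn{\Delta^k_{cross} = \frac{\hat y_k(a_{n+1}) - \hat y_k(a_n)}
#'       {a_{n+1} - a_n} \times \frac{100\%}{\hat y_k(a_n)}}
#' in percent mode; absolute mode omits the \eqn{100/\hat y_k(a_n)} factor.
#' The output grid is the input grid's midpoints.
#'
#' @param curve a \code{centile_curve} from \code{\link{evaluate_centile}},
#'   or any data frame with \code{age} (uniform grid) and \code{value} (> 0)
#'   columns.
#' @param units output units mode.
#' @return an unsmoothed \code{\link{rate_curve}} with provenance
#'   \code{"cross"}.
#' @export
differentiate_centile <- function(curve, units = c("percent", "absolute")) {
  units <- match.arg(units)
  stopifnot(is.data.frame(curve), all(c("age", "value") %in% names(curve)))
  a <- curve$age; v <- curve$value
  if (length(a) < 2) stop("need at least two grid ages")
  h <- diff(a)
  if (any(h <= 0) || diff(range(h)) > 1e-9)
    stop("centile curve must be on a uniform, strictly increasing age grid")
  if (any(v <= 0)) stop("centile values must be strictly positive")
  n <- length(a)
  dv <- diff(v) / h
  left <- v[-n]
  vals <- if (units == "percent") dv * 100 / left else dv
  rate_curve((a[-n] + a[-1]) / 2, vals, units_mode = units,
             k = attr(curve, "k") %||% 0.5, provenance = "cross",
             ref_values = left)
}

#' Moving-average smoothing of a rate curve
#'
#' Boxcar (moving-average) filter over all grid points within ±\code{span}
#' years of each age; differentiation sharpens noise, so the default span
#' of ±2.5 years restores a stable curve. At the grid boundaries the window
#' truncates to the available points.
#'
#' @param rate a \code{\link{rate_curve}}.
#' @param span_years half-window in years.
#' @return the smoothed \code{\link{rate_curve}}; if the span is below the
#'   grid spacing the input is returned unchanged with a warning.
#' @export
smooth_rate <- function(rate, span_years = 2.5) {
  stopifnot(inherits(rate, "rate_curve"))
  h <- rate$age[2] - rate$age[1]
  if (span_years < h) {
    warning("smoothing span is below the grid spacing; returning unsmoothed")
    return(rate)
  }
  w <- floor(span_years / h + 1e-9)
  n <- nrow(rate)
  cs <- cumsum(c(0, rate$rate))
  lo <- pmax(seq_len(n) - w, 1L)
  hi <- pmin(seq_len(n) + w, n)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  rate_curve(rate$age, sm, units_mode = attr(rate, "units_mode"),
             k = attr(rate, "k"), provenance = attr(rate, "provenance"),
             smoothed = TRUE, span = span_years,
             ref_values = attr(rate, "ref_values"))
}

#' Per-subject annualized rates of change
#'
#' The longitudinal rate for each subject: follow-up minus baseline divided
#' by the interscan interval, \code{(y1 - y0) / (age1 - age0)}, with the
#' percent-of-baseline form and the mid-age \code{(age0 + age1)/2} attached.
#'
#' @param cohort a \code{\link{as_longitudinal_cohort}} table.
#' @return data frame of class \code{rate_sample}: subject_id, sex, site,
#'   mid_age, interval, y0, rate (units/year), rate_percent (\%/year).
#' @export
annualized_rates <- function(cohort) {
  cohort <- as_longitudinal_cohort(cohort)
  interval <- cohort$age1 - cohort$age0
  rate <- (cohort$y1 - cohort$y0) / interval
  structure(data.frame(subject_id = cohort$subject_id, sex = cohort$sex,
                       site = cohort$site,
                       mid_age = (cohort$age0 + cohort$age1) / 2,
                       interval = interval, y0 = cohort$y0,
                       rate = rate, rate_percent = rate / cohort$y0 * 100),
            class = c("rate_sample", "data.frame"))
}

#' Normative chart of longitudinal rates versus age
#'
#' Fits a location-scale normative model of the annualized rate as a smooth
#' function of mid-age, separately per sex-by-site stratum. Rates change
#' sign, so the positive-support BCT family does not apply; a Gaussian
#' location-scale model with penalized-spline mean and (log-link) scale is
#' used (via \code{mgcv::gam} with the \code{gaulss} family). The median
#' curve of this fit is the "longitudinal" rate curve used in
#' cross-vs-longitudinal comparisons.
#'
#' @param rates a \code{rate_sample} from \code{\link{annualized_rates}}.
#' @param k_mean,k_scale spline basis dimensions for the mean and scale.
#' @param min_n strata with fewer rates are skipped with a warning.
#' @return object of class \code{rate_chart}: per-stratum \code{gam} fits
#'   plus age domains.
#' @export
fit_rate_chart <- function(rates, k_mean = 8L, k_scale = 5L, min_n = 50L) {
  stopifnot(inherits(rates, "rate_sample"))
  keys <- stratum_key(rates$sex, rates$site)
  fits <- list()
  for (key in sort(unique(keys))) {
    idx <- keys == key
    if (sum(idx) < min_n) {
      warning(sprintf("stratum '%s' has %d < %d rates; skipped",
                      key, sum(idx), min_n))
      next
    }
    dat <- data.frame(rate = rates$rate[idx], mid_age = rates$mid_age[idx])
    km <- min(k_mean, length(unique(dat$mid_age)) - 1L)
    ks <- min(k_scale, km)
    fit <- mgcv::gam(list(rate ~ s(mid_age, k = km),
                          ~ s(mid_age, k = ks)),
                     family = mgcv::gaulss(), data = dat, method = "REML")
    fits[[key]] <- list(gam = fit, age_domain = range(dat$mid_age),
                        n = sum(idx))
  }
  if (!length(fits)) stop("no stratum had enough rates to fit")
  structure(list(strata = fits), class = "rate_chart")
}

#' Evaluate the median (or any percentile) curve of a rate chart
#'
#' @param chart a \code{rate_chart}.
#' @param ages age grid; clamped to the stratum's fitted domain.
#' @param stratum stratum key; may be omitted for a single-stratum chart.
#' @param k percentile of the Gaussian location-scale fit (0.5 gives the
#'   fitted mean curve).
#' @return a \code{\link{rate_curve}} with provenance \code{"longitudinal"}.
#' @export
evaluate_rate_chart <- function(chart, ages, stratum = NULL, k = 0.5) {
  stopifnot(inherits(chart, "rate_chart"))
  if (is.null(stratum)) {
    if (length(chart$strata) != 1L)
      stop("chart has multiple strata; specify 'stratum'")
    stratum <- names(chart$strata)[1L]
  }
  f <- chart$strata[[stratum]]
  if (is.null(f)) stop(sprintf("unknown stratum '%s'", stratum))
  a <- pmin(pmax(ages, f$age_domain[1]), f$age_domain[2])
  pr <- stats::predict(f$gam, newdata = data.frame(mid_age = a),
                       type = "response")
  mu <- pr[, 1]
  sd <- 1 / pr[, 2]  # gaulss second fitted column is the precision 1/sigma
  rate_curve(ages, stats::qnorm(k, mean = mu, sd = sd),
             units_mode = "absolute", k = k, provenance = "longitudinal")
}

#' Percentage difference between cross-sectional and longitudinal rates
#'
#' Resamples both curves onto a common uniform grid (linear interpolation)
#' and computes
#' \deqn{pd(a) = \frac{|\Delta_{long}(a)| - |\Delta_{cross}(a)|}
#'       {|\Delta_{long}(a)|} \times 100,}
#' so positive values mean the cross-sectional chart underestimates the
#' magnitude of change. The summary reports the maximum and its age over
#' the interior grid (a boundary margin is excluded, matching the
#' smoothing span); grid ages where the longitudinal rate is numerically
#' zero are masked from the summary and reported.
#'
#' @param cross,long \code{\link{rate_curve}}s in the same units mode.
#' @param boundary_margin years excluded at each end of the common grid for
#'   the summary statistics.
#' @param eps magnitude below which the longitudinal rate is treated as
#'   zero and masked.
#' @return list: \code{curve} (data frame age, percent_difference, masked),
#'   \code{max_percent_difference}, \code{age_at_max}, \code{masked_ages}.
#' @export
percent_difference <- function(cross, long, boundary_margin = 2.5,
                               eps = 1e-12) {
  stopifnot(inherits(cross, "rate_curve"), inherits(long, "rate_curve"))
  if (!identical(attr(cross, "units_mode"), attr(long, "units_mode")))
    stop("curves must share a units mode")
  lo <- max(min(cross$age), min(long$age))
  hi <- min(max(cross$age), max(long$age))
  if (hi <= lo) stop("curves do not overlap in age")
  h <- min(cross$age[2] - cross$age[1], long$age[2] - long$age[1])
  grid <- seq(lo, hi, by = h)
  cr <- stats::approx(cross$age, cross$rate, xout = grid)$y
  lg <- stats::approx(long$age, long$rate, xout = grid)$y
  masked <- abs(lg) < eps
  pd <- ifelse(masked, NA_real_, (abs(lg) - abs(cr)) / abs(lg) * 100)
  interior <- grid >= lo + boundary_margin & grid <= hi - boundary_margin &
    !masked
  if (!any(interior)) interior <- !masked
  imax <- which(interior)[which.max(abs(pd[interior]))]
  list(curve = data.frame(age = grid, percent_difference = pd,
                          masked = masked),
       max_percent_difference = pd[imax],
       age_at_max = grid[imax],
       masked_ages = grid[masked])
}

#' Cross-sectional (GLM) versus mixed-model (LME) age slopes
#'
#' Contrasts the ordinary least-squares slope of baseline value on baseline
#' age (the purely cross-sectional estimate) with the fixed age slope of a
#' random-intercept linear mixed model fitted by maximum likelihood to the
#' stacked baseline and follow-up measurements, which partially controls
#' for repeated measurements. On a cohort-effect generator the LME slope
#' lies between the GLM slope and the mean within-person slope.
#'
#' @param cohort a \code{\link{as_longitudinal_cohort}} table.
#' @param by_stratum fit separately per sex-by-site cell (default) or
#'   pooled.
#' @return data frame per stratum: glm_slope, glm_se, lme_slope, lme_se,
#'   difference, n, singular flag.
#' @export
lme_vs_glm_rates <- function(cohort, by_stratum = TRUE) {
  cohort <- as_longitudinal_cohort(cohort)
  keys <- if (by_stratum) stratum_key(cohort$sex, cohort$site)
          else rep("all", nrow(cohort))
  res <- lapply(sort(unique(keys)), function(key) {
    sub <- cohort[keys == key, , drop = FALSE]
    gl <- stats::lm(y0 ~ age0, data = sub)
    stacked <- data.frame(
      subject_id = rep(sub$subject_id, 2L),
      age = c(sub$age0, sub$age1),
      y = c(sub$y0, sub$y1))
    lf <- lme4::lmer(y ~ age + (1 | subject_id), data = stacked, REML = FALSE,
                     control = lme4::lmerControl(calc.derivs = FALSE))
    glm_slope <- unname(stats::coef(gl)["age0"])
    lme_slope <- unname(lme4::fixef(lf)["age"])
    data.frame(stratum = key,
               glm_slope = glm_slope,
               glm_se = unname(sqrt(diag(stats::vcov(gl)))["age0"]),
               lme_slope = lme_slope,
               lme_se = unname(sqrt(diag(as.matrix(stats::vcov(lf))))[2]),
               difference = lme_slope - glm_slope,
               n = nrow(sub),
               singular = lme4::isSingular(lf))
  })
  do.call(rbind, res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
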