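#' The Box-Cox t distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the four-parameter Box-Cox t (BCT) distribution used in normative
#' centile (growth-chart) modelling. A positive response \eqn{Y} follows a
#' BCT distribution if the Box-Cox transform
#' \deqn{z = \frac{(y/\mu)^\nu - 1}{\nu\sigma} \quad (\nu \neq 0), \qquad
#'       z = \frac{\log(y/\mu)}{\sigma} \quad (\nu = 0)}
#' follows a t distribution with \code{tau} degrees of freedom, truncated so
#' that the support of \eqn{Y} is \eqn{(0, \infty)}.
#'
#' \code{mu} (> 0) is the (approximate) median on the response scale,
#' \code{sigma} (> 0) the relative dispersion (approximately the coefficient
#' of variation for small \code{sigma}), \code{nu} (real) the Box-Cox power
#' controlling skewness, and \code{tau} (> 0) the degrees of freedom
#' controlling tail weight. As \code{tau} grows large the BCT converges to
#' the Box-Cox normal (LMS) distribution.
#'
#' The truncation constant is \eqn{c = F_T(1/(\sigma|\nu|); \tau)} (equal to
#' 1 when \eqn{\nu = 0}); the CDF is
#' \eqn{F(y) = (F_T(z) - F_T(-1/(\sigma|\nu|)) \cdot [\nu > 0]) / c}.
#'
#' @param x,q vector of (strictly positive) quantiles.
#' @param p vector of probabilities in (0, 1).
#' @param n number of random draws.
#' @param mu location parameter (> 0), phenotype units.
#' @param sigma relative scale parameter (> 0).
#' @param nu Box-Cox power (skewness) parameter.
#' @param tau degrees of freedom (> 0).
#' @param log,log.p logical; if TRUE, probabilities/densities are given on
#'   the log scale.
#'
#' @return \code{dbct} the density, \code{pbct} the CDF, \code{qbct} the
#'   quantile function, \code{rbct} random draws. All vectorized and
#'   recycled to the longest argument.
#'
#' @examples
#' qbct(0.5, mu = 100, sigma = 0.05, nu = 1, tau = 10)  # ~ 100
#' pbct(qbct(0.84, 100, 0.05, 1, 10), 100, 0.05, 1, 10) # 0.84
#' @name bct
NULL

bct_check <- function(mu, sigma, tau) {
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("'mu' must be finite and > 0")
  if (any(!is.finite(sigma)) || any(sigma <= 0)) stop("'sigma' must be finite and > 0")
  if (any(!is.finite(tau)) || any(tau <= 0)) stop("'tau' must be finite and > 0")
  invisible(TRUE)
}

# z-transform; elementwise, nu == 0 handled by the log limit
bct_z <- function(y, mu, sigma, nu) {
  ifelse(nu == 0, log(y / mu) / sigma, ((y / mu)^nu - 1) / (nu * sigma))
}

# truncation constant c = F_T(1/(sigma|nu|); tau); 1 when nu == 0
bct_trunc <- function(sigma, nu, tau) {
  ifelse(nu == 0, 1, stats::pt(1 / (sigma * abs(nu)), df = tau))
}

#' @rdname bct
#' @export
dbct <- function(x, mu, sigma, nu = 0, tau = 10, log = FALSE) {
  bct_check(mu, sigma, tau)
  if (any(x <= 0)) stop("'x' must be > 0 (BCT support is the positive reals)")
  k <- max(length(x), length(mu), length(sigma), length(nu), length(tau))
  x <- rep_len(x, k); mu <- rep_len(mu, k); sigma <- rep_len(sigma, k)
  nu <- rep_len(nu, k); tau <- rep_len(tau, k)
  z <- bct_z(x, mu, sigma, nu)
  ll <- (nu - 1) * base::log(x) - nu * base::log(mu) - base::log(sigma) +
    stats::dt(z, df = tau, log = TRUE) -
    base::log(bct_trunc(sigma, nu, tau))
  if (log) ll else exp(ll)
}

#' @rdname bct
#' @export
pbct <- function(q, mu, sigma, nu = 0, tau = 10, log.p = FALSE) {
  bct_check(mu, sigma, tau)
  if (any(q <= 0)) stop("'q' must be > 0 (BCT support is the positive reals)")
  k <- max(length(q), length(mu), length(sigma), length(nu), length(tau))
  q <- rep_len(q, k); mu <- rep_len(mu, k); sigma <- rep_len(sigma, k)
  nu <- rep_len(nu, k); tau <- rep_len(tau, k)
  z <- bct_z(q, mu, sigma, nu)
  cc <- bct_trunc(sigma, nu, tau)
  lower <- ifelse(nu > 0, stats::pt(-1 / (sigma * abs(nu)), df = tau), 0)
  p <- (stats::pt(z, df = tau) - lower) / cc
  p <- pmin(pmax(p, 0), 1)
  if (log.p) base::log(p) else p
}

#' @rdname bct
#' @export
qbct <- function(p, mu, sigma, nu = 0, tau = 10) {
  bct_check(mu, sigma, tau)
  if (any(p <= 0 | p >= 1)) stop("'p' must lie strictly inside (0, 1)")
  k <- max(length(p), length(mu), length(sigma), length(nu), length(tau))
  p <- rep_len(p, k); mu <- rep_len(mu, k); sigma <- rep_len(sigma, k)
  nu <- rep_len(nu, k); tau <- rep_len(tau, k)
  cc <- bct_trunc(sigma, nu, tau)
  # invert the truncated-t CDF: left truncation for nu > 0, right for nu < 0
  z <- ifelse(nu > 0,
              stats::qt(1 - (1 - p) * cc, df = tau),
              stats::qt(p * cc, df = tau))
  ifelse(nu == 0, mu * exp(sigma * z), mu * (nu * sigma * z + 1)^(1 / nu))
}

#' @rdname bct
#' @export
rbct <- function(n, mu, sigma, nu = 0, tau = 10) {
  qbct(stats::runif(n), mu = mu, sigma = sigma, nu = nu, tau = tau)
}
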