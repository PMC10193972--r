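# Independent oracles and small fixture builders shared across the suite.

# numerical quadrature of the BCT density over (0, Inf) via the log
# substitution y = mu * exp(u), with tau-adaptive bounds so both heavy-tail
# and near-Gaussian cases resolve
bct_mass_oracle <- function(mu, sigma, nu, tau) {
  f <- function(y) dbct(y, mu, sigma, nu, tau)
  g <- function(u) f(mu * exp(u)) * mu * exp(u)
  b <- min(600, 2 * sigma * stats::qt(1 - 1e-10, tau))
  segs <- list(c(-690, -b), c(-b, 0), c(0, b), c(b, 690))
  sum(vapply(segs, function(lim)
    stats::integrate(g, lim[1], lim[2], rel.tol = 1e-10,
                     subdivisions = 5000L)$value, numeric(1)))
}

# quantile by numerical inversion of the integrated density (independent of
# the closed-form quantile under test)
bct_quantile_oracle <- function(p, mu, sigma, nu, tau) {
  f <- function(y) dbct(y, mu, sigma, nu, tau)
  cdf <- function(q) stats::integrate(f, mu * 1e-6, q, rel.tol = 1e-12)$value
  stats::uniroot(function(q) cdf(q) - p, c(mu * 0.2, mu * 5), tol = 1e-10)$root
}

# Box-Cox normal (LMS) quantile: the tau -> Inf limit of the BCT
bcn_quantile_oracle <- function(p, mu, sigma, nu) {
  cc <- if (nu == 0) 1 else stats::pnorm(1 / (sigma * abs(nu)))
  z <- if (nu > 0) stats::qnorm(1 - (1 - p) * cc) else stats::qnorm(p * cc)
  if (nu == 0) mu * exp(sigma * z) else mu * (nu * sigma * z + 1)^(1 / nu)
}

# literal Benjamini-Hochberg step-up from its definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# single-stratum cohort helper: collapse sex/site so fits pool everyone
single_stratum <- function(cohort) {
  cohort$sex <- "F"
  cohort$site <- "site1"
  cohort
}

# the canonical parameter-recovery generator: baseline exactly BCT with
# mu(a) = 100 - 0.5 a, sigma = 0.05, nu = 1, tau = 10, ages U(47, 80)
recovery_config <- function(n = 5000, seed = 42) {
  simulation_config(n_subjects = n,
                    curve = median_curve("linear", intercept = 100,
                                         slope = -0.5),
                    sigma_rel = 0.05, nu = 1, tau = 10,
                    slope_sd = 0, noise_sd = 0, seed = seed)
}

# hand-built prediction record table
make_records <- function(ae, y0 = 100, method = "median-centile") {
  n <- length(ae)
  data.frame(subject_id = seq_len(n), method = method, k = 0.5,
             age0 = 60, age1 = 62, y0 = y0, y1_pred = y0, y1_obs = y0 + ae,
             clamped = FALSE, ae = ae, ae_norm = ae / y0)
}
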