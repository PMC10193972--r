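# Penalized B-spline (P-spline) building blocks used by the centile fitter.
# Cubic B-spline basis on equally spaced knots with a difference penalty;
# smoothing parameters are chosen to hit a fixed effective degrees of
# freedom, so fits are deterministic given the data.

# Equally spaced cubic B-spline basis covering [xmin, xmax].
ps_basis <- function(x, xmin, xmax, nbasis = 8L, degree = 3L) {
  if (nbasis <= degree) stop("nbasis must exceed the spline degree")
  ndx <- nbasis - degree
  dx <- (xmax - xmin) / ndx
  knots <- seq(xmin - degree * dx, xmax + degree * dx, by = dx)
  # evaluation is only valid inside [xmin, xmax]; callers clamp first
  splines::splineDesign(knots, pmin(pmax(x, xmin), xmax), ord = degree + 1L)
}

# D'D for a difference penalty of the given order.
ps_penalty <- function(nbasis, order = 2L) {
  D <- diff(diag(nbasis), differences = order)
  crossprod(D)
}

# Solve M x = y with a ridge that escalates until the system is
# numerically nonsingular (degenerate designs, e.g. a single distinct age).
ps_safe_solve <- function(M, y) {
  scale <- 1 + mean(abs(diag(M)))
  for (r in 10^seq(-8, 4, by = 2)) {
    out <- tryCatch({
      Mr <- M
      diag(Mr) <- diag(Mr) + r * scale
      solve(Mr, y)
    }, error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  stop("penalized spline system is singular")
}

# Effective df of the penalized weighted smoother at a given lambda.
ps_edf <- function(lambda, BtWB, P) {
  sum(diag(ps_safe_solve(BtWB + lambda * P, BtWB)))
}

# Smallest-magnitude lambda giving the target effective df (edf is
# monotone decreasing in lambda). Deterministic bisection on log10(lambda).
ps_lambda_for_df <- function(BtWB, P, df) {
  lo <- -10; hi <- 12
  f <- function(l10) ps_edf(10^l10, BtWB, P) - df
  flo <- f(lo); fhi <- f(hi)
  if (flo <= 0) return(10^lo)  # even unpenalized fit has <= df
  if (fhi >= 0) return(10^hi)
  10^uniroot(f, c(lo, hi), tol = 1e-4)$root
}

# One penalized iteratively-reweighted least squares step:
# minimize sum w (z - B b)^2 + lambda b' P b.
ps_solve <- function(B, w, z, lambda, P) {
  BtWB <- crossprod(B, B * w)
  ps_safe_solve(BtWB + lambda * P, crossprod(B, w * z))
}
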