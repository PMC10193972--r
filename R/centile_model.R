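#' Smooth-term configuration for centile fitting
#'
#' Controls the semiparametric structure of the Box-Cox t normative model:
#' \eqn{\mu(age)} and \eqn{\sigma(age)} are penalized cubic B-splines with
#' log links (guaranteeing positivity), while the skewness \eqn{\nu}
#' (identity link) and degrees of freedom \eqn{\tau} (log link, bounded to
#' \eqn{[1.01, 10^6]} to avoid the Cauchy-tail region) are age-constant
#' scalars. Smoothing parameters are chosen to hit fixed effective degrees
#' of freedom, so the optimizer is fully deterministic.
#'
#' @param nbasis_mu,nbasis_sigma number of B-spline basis functions for the
#'   location and scale smooths.
#' @param df_mu,df_sigma target effective degrees of freedom for the
#'   location and scale smooths.
#' @param penalty_order order of the difference penalty.
#' @param nu_start,tau_start starting values for the shape parameters.
#' @param maxit maximum number of outer backfitting cycles.
#' @param tol relative global-deviance convergence tolerance.
#' @return an object of class \code{chart_spec}.
#' @export
chart_spec <- function(nbasis_mu = 8L, df_mu = 5, nbasis_sigma = 8L,
                       df_sigma = 3, penalty_order = 2L,
                       nu_start = 1, tau_start = 10,
                       maxit = 200L, tol = 1e-6) {
  stopifnot(nbasis_mu > 3, nbasis_sigma > 3, df_mu >= 1, df_sigma >= 1,
            maxit >= 1, tol > 0)
  structure(list(nbasis_mu = as.integer(nbasis_mu), df_mu = df_mu,
                 nbasis_sigma = as.integer(nbasis_sigma), df_sigma = df_sigma,
                 penalty_order = as.integer(penalty_order),
                 nu_start = nu_start, tau_start = tau_start,
                 maxit = as.integer(maxit), tol = tol),
            class = "chart_spec")
}

# per-observation BCT log-likelihood on the linear-predictor scale
bct_loglik_vec <- function(y, eta_mu, eta_sigma, nu, tau) {
  eta_sigma <- pmin(pmax(eta_sigma, -12), 4)
  eta_mu <- pmin(pmax(eta_mu, -30), 30)
  dbct(y, exp(eta_mu), exp(eta_sigma), nu, tau, log = TRUE)
}

# Newton step for one spline term via numerically differentiated
# per-observation log-likelihood; returns updated coefficients.
bct_spline_step <- function(y, B, beta, ll_at, lambda, P, hstep = 1e-4) {
  eta <- drop(B %*% beta)
  ll0 <- ll_at(eta)
  llp <- ll_at(eta + hstep)
  llm <- ll_at(eta - hstep)
  u <- (llp - llm) / (2 * hstep)
  w <- -(llp - 2 * ll0 + llm) / hstep^2
  w[!is.finite(w) | w < 1e-10] <- 1e-10
  u[!is.finite(u)] <- 0
  z <- eta + u / w
  drop(ps_solve(B, w, z, lambda, P))
}

# deterministic cyclic (RS-type) backfitting for one stratum
fit_bct_stratum <- function(y, age, spec) {
  n <- length(y)
  xmin <- min(age); xmax <- max(age)
  if (xmax - xmin < 1e-8) { xmin <- xmin - 0.5; xmax <- xmax + 0.5 }
  Bm <- ps_basis(age, xmin, xmax, spec$nbasis_mu)
  Bs <- ps_basis(age, xmin, xmax, spec$nbasis_sigma)
  Pm <- ps_penalty(spec$nbasis_mu, spec$penalty_order)
  Ps <- ps_penalty(spec$nbasis_sigma, spec$penalty_order)

  # initialization: Gaussian penalized spline on log(y); constant sigma
  ly <- log(y)
  lam0 <- ps_lambda_for_df(crossprod(Bm), Pm, spec$df_mu)
  beta_mu <- drop(ps_solve(Bm, rep(1, n), ly, lam0, Pm))
  s0 <- stats::sd(ly - drop(Bm %*% beta_mu))
  s0 <- max(s0, 1e-4)
  beta_sigma <- rep(log(s0), spec$nbasis_sigma)  # B-splines sum to one
  nu <- spec$nu_start
  ltau <- log(spec$tau_start)

  dev_old <- Inf; converged <- FALSE; it <- 0
  lam_mu <- lam0; lam_sigma <- NA_real_
  for (it in seq_len(spec$maxit)) {
    eta_s <- drop(Bs %*% beta_sigma)
    # mu step
    llm_fun <- function(em) bct_loglik_vec(y, em, eta_s, nu, exp(ltau))
    eta_m <- drop(Bm %*% beta_mu)
    lp <- llm_fun(eta_m + 1e-4); lm <- llm_fun(eta_m - 1e-4); l0 <- llm_fun(eta_m)
    u <- (lp - lm) / 2e-4
    w <- -(lp - 2 * l0 + lm) / 1e-8
    w[!is.finite(w) | w < 1e-10] <- 1e-10
    u[!is.finite(u)] <- 0
    lam_mu <- ps_lambda_for_df(crossprod(Bm, Bm * w), Pm, spec$df_mu)
    beta_mu <- drop(ps_solve(Bm, w, eta_m + u / w, lam_mu, Pm))
    eta_m <- drop(Bm %*% beta_mu)

    # sigma step
    lls_fun <- function(es) bct_loglik_vec(y, eta_m, es, nu, exp(ltau))
    lp <- lls_fun(eta_s + 1e-4); lm <- lls_fun(eta_s - 1e-4); l0 <- lls_fun(eta_s)
    u <- (lp - lm) / 2e-4
    w <- -(lp - 2 * l0 + lm) / 1e-8
    w[!is.finite(w) | w < 1e-10] <- 1e-10
    u[!is.finite(u)] <- 0
    lam_sigma <- ps_lambda_for_df(crossprod(Bs, Bs * w), Ps, spec$df_sigma)
    beta_sigma <- drop(ps_solve(Bs, w, eta_s + u / w, lam_sigma, Ps))
    eta_s <- drop(Bs %*% beta_sigma)

    # scalar shape steps: exact 1-D maximization on safeguarded brackets
    nu <- stats::optimize(function(v) sum(bct_loglik_vec(y, eta_m, eta_s, v, exp(ltau))),
                          c(-4, 4), maximum = TRUE, tol = 1e-6)$maximum
    ltau <- stats::optimize(function(lt) sum(bct_loglik_vec(y, eta_m, eta_s, nu, exp(lt))),
                            c(log(1.01), log(1e6)), maximum = TRUE, tol = 1e-6)$maximum

    dev <- -2 * sum(bct_loglik_vec(y, eta_m, eta_s, nu, exp(ltau)))
    if (is.finite(dev_old) &&
        abs(dev_old - dev) / (abs(dev_old) + 0.1) < spec$tol) {
      converged <- TRUE; dev_old <- dev; break
    }
    dev_old <- dev
  }

  list(beta_mu = beta_mu, beta_sigma = beta_sigma,
       nu = nu, tau = exp(ltau),
       xmin = xmin, xmax = xmax,
       nbasis_mu = spec$nbasis_mu, nbasis_sigma = spec$nbasis_sigma,
       lambda_mu = lam_mu, lambda_sigma = lam_sigma,
       deviance = dev_old, iterations = it, converged = converged,
       n = n, age_domain = c(xmin, xmax))
}

stratum_key <- function(sex, site) paste(as.character(sex), as.character(site), sep = ".")

#' Fit a Box-Cox t normative centile model
#'
#' Fits age-varying BCT parameter curves separately within each sex-by-site
#' stratum by cyclic backfitting over \eqn{(\mu, \sigma, \nu, \tau)}:
#' penalized iteratively reweighted B-spline updates for the log-linked
#' \eqn{\mu(age)} and \eqn{\sigma(age)} smooths, and exact bounded 1-D
#' maximizations for the scalar \eqn{\nu} and \eqn{\log\tau}. Convergence is
#' declared when the relative change in global deviance falls below
#' \code{spec$tol}; non-converged strata are returned with
#' \code{converged = FALSE} and a warning.
#'
#' @param cohort a longitudinal cohort table (see
#'   \code{\link{as_longitudinal_cohort}}).
#' @param column phenotype column to model (\code{"y0"} baseline or
#'   \code{"y1"} follow-up); ages are taken from the matching age column.
#' @param spec a \code{\link{chart_spec}}.
#' @param min_n strata with fewer observations are skipped with a warning.
#' @return an object of class \code{centile_model}: per-stratum basis
#'   ranges, coefficient vectors, shape parameters and fit metadata.
#' @export
fit_centile_model <- function(cohort, column = "y0", spec = chart_spec(),
                              min_n = 50L) {
  stopifnot(inherits(spec, "chart_spec"))
  cohort <- as_longitudinal_cohort(cohort)
  age_column <- switch(column, y0 = "age0", y1 = "age1",
                       stop("'column' must be \"y0\" or \"y1\""))
  y_all <- cohort[[column]]
  if (any(y_all <= 0)) stop("all phenotype values must be > 0")
  keys <- stratum_key(cohort$sex, cohort$site)
  fits <- list()
  for (key in sort(unique(keys))) {
    idx <- keys == key
    if (sum(idx) < min_n) {
      warning(sprintf("stratum '%s' has %d < %d observations; skipped",
                      key, sum(idx), min_n))
      next
    }
    fits[[key]] <- fit_bct_stratum(y_all[idx], cohort[[age_column]][idx], spec)
    if (!fits[[key]]$converged)
      warning(sprintf("stratum '%s' did not converge in %d iterations",
                      key, spec$maxit))
  }
  if (!length(fits)) stop("no stratum had enough observations to fit")
  structure(list(strata = fits, spec = spec, column = column,
                 age_column = age_column,
                 subjects = sort(unique(cohort$subject_id[keys %in% names(fits)]))),
            class = "centile_model")
}

#' @export
print.centile_model <- function(x, ...) {
  cat(sprintf("BCT centile model on '%s' (%d strata)\n", x$column,
              length(x$strata)))
  for (key in names(x$strata)) {
    f <- x$strata[[key]]
    cat(sprintf("  %-14s n=%5d  age [%.1f, %.1f]  nu=%.3f tau=%.1f  %s (%d it)\n",
                key, f$n, f$xmin, f$xmax, f$nu, f$tau,
                if (f$converged) "converged" else "NOT converged", f$iterations))
  }
  invisible(x)
}

model_stratum <- function(model, stratum) {
  if (is.null(stratum)) {
    if (length(model$strata) != 1L)
      stop("model has multiple strata; specify 'stratum'")
    return(model$strata[[1L]])
  }
  f <- model$strata[[stratum]]
  if (is.null(f)) stop(sprintf("unknown stratum '%s'", stratum))
  f
}

# BCT parameters at given ages for one stratum
params_at_age <- function(fit, ages, rule = c("clamp", "error")) {
  rule <- match.arg(rule)
  out <- ages < fit$xmin - 1e-9 | ages > fit$xmax + 1e-9
  if (any(out)) {
    if (rule == "error")
      stop("ages outside the model age domain [",
           signif(fit$xmin, 6), ", ", signif(fit$xmax, 6), "]")
    ages <- pmin(pmax(ages, fit$xmin), fit$xmax)
  }
  Bm <- ps_basis(ages, fit$xmin, fit$xmax, fit$nbasis_mu)
  Bs <- ps_basis(ages, fit$xmin, fit$xmax, fit$nbasis_sigma)
  data.frame(age = ages,
             mu = exp(pmin(pmax(drop(Bm %*% fit$beta_mu), -30), 30)),
             sigma = exp(pmin(pmax(drop(Bs %*% fit$beta_sigma), -12), 4)),
             nu = fit$nu, tau = fit$tau,
             clamped = out)
}

#' Evaluate a fitted percentile curve
#'
#' Returns the k-th percentile curve \eqn{\hat y_k(age)} of a fitted
#' centile model over an age grid. Curves are monotone in \code{k} at every
#' age by construction (quantiles of a single fitted distribution).
#'
#' @param model a \code{centile_model}.
#' @param k percentile in (0, 1).
#' @param ages numeric age grid.
#' @param stratum stratum key (\code{"<sex>.<site>"}); may be omitted for a
#'   single-stratum model.
#' @param rule \code{"error"} to reject ages outside the fitted age domain,
#'   \code{"clamp"} to evaluate at the nearest domain edge.
#' @return a data frame (age, value) of class \code{centile_curve} with the
#'   percentile and stratum attached as attributes.
#' @export
evaluate_centile <- function(model, k = 0.5, ages, stratum = NULL,
                             rule = c("error", "clamp")) {
  stopifnot(inherits(model, "centile_model"))
  rule <- match.arg(rule)
  if (length(k) != 1L || k <= 0 || k >= 1) stop("'k' must be one value in (0, 1)")
  fit <- model_stratum(model, stratum)
  pa <- params_at_age(fit, ages, rule = if (rule == "error") "error" else "clamp")
  structure(data.frame(age = ages,
                       value = qbct(k, pa$mu, pa$sigma, pa$nu, pa$tau)),
            k = k, stratum = stratum, class = c("centile_curve", "data.frame"))
}

#' Baseline centile of an observation
#'
#' Ranks a baseline measurement against the fitted chart:
#' \eqn{k = F_{BCT}(y_0;\ \theta(age_0))}, clamped to \eqn{[0.01, 0.99]} so
#' that individualized-centile predictions cannot run off the chart.
#'
#' @param model a \code{centile_model}.
#' @param y0 positive baseline value(s).
#' @param age0 age(s) at baseline.
#' @param stratum stratum key, as in \code{\link{evaluate_centile}}.
#' @param clamp two-sided clamp band for the returned percentile.
#' @return percentile(s) in \code{[clamp[1], clamp[2]]}.
#' @export
baseline_percentile <- function(model, y0, age0, stratum = NULL,
                                clamp = c(0.01, 0.99)) {
  stopifnot(inherits(model, "centile_model"), all(y0 > 0))
  fit <- model_stratum(model, stratum)
  pa <- params_at_age(fit, age0, rule = "clamp")
  k <- pbct(y0, pa$mu, pa$sigma, pa$nu, pa$tau)
  pmin(pmax(k, clamp[1]), clamp[2])
}

#' Normalized quantile residuals
#'
#' Computes \eqn{r_i = \Phi^{-1}(F_{BCT}(y_i;\ \theta(age_i)))} for every
#' observation in the fitted strata. Under a correctly specified model the
#' residuals are standard normal; the returned summary (mean, SD, skewness,
#' excess kurtosis) and the sorted residuals support QQ diagnostics.
#'
#' @param model a \code{centile_model}.
#' @param cohort the cohort to evaluate (typically the training table).
#' @param column phenotype column; defaults to the fitted column.
#' @return data frame (subject_id, stratum, age, y, cdf, z) with a
#'   \code{summary} attribute.
#' @export
z_residuals <- function(model, cohort, column = model$column) {
  cohort <- as_longitudinal_cohort(cohort)
  age_column <- switch(column, y0 = "age0", y1 = "age1",
                       stop("'column' must be \"y0\" or \"y1\""))
  keys <- stratum_key(cohort$sex, cohort$site)
  keep <- keys %in% names(model$strata)
  cohort <- cohort[keep, , drop = FALSE]; keys <- keys[keep]
  out <- vector("list", length(model$strata))
  for (i in seq_along(model$strata)) {
    key <- names(model$strata)[i]
    idx <- which(keys == key)
    if (!length(idx)) next
    fit <- model$strata[[key]]
    pa <- params_at_age(fit, cohort[[age_column]][idx], rule = "clamp")
    cdf <- pbct(cohort[[column]][idx], pa$mu, pa$sigma, pa$nu, pa$tau)
    cdf <- pmin(pmax(cdf, 1e-12), 1 - 1e-12)
    out[[i]] <- data.frame(subject_id = cohort$subject_id[idx], stratum = key,
                           age = cohort[[age_column]][idx],
                           y = cohort[[column]][idx],
                           cdf = cdf, z = stats::qnorm(cdf))
  }
  res <- do.call(rbind, out)
  z <- res$z
  m <- mean(z); s <- stats::sd(z)
  attr(res, "summary") <- list(
    n = length(z), mean = m, sd = s,
    skewness = mean((z - m)^3) / s^3,
    excess_kurtosis = mean((z - m)^4) / s^4 - 3)
  res
}

#' Bootstrap confidence bands for chart-derived curves
#'
#' Resamples subjects with replacement within each stratum, refits the
#' centile model, re-evaluates the requested curve (a percentile curve, or
#' its smoothed absolute/percent rate-of-change), and returns pointwise
#' percentile-bootstrap bands (default the 25th and 75th percentiles of the
#' bootstrap distribution, with B = 500 resamples). Deterministic given
#' \code{seed}; bootstrap refits that error out or fail to converge are
#' dropped and counted, with a warning above 20\% failures.
#'
#' @param cohort training cohort.
#' @param column phenotype column (\code{"y0"} or \code{"y1"}).
#' @param spec a \code{\link{chart_spec}}.
#' @param stratum stratum key; required for multi-stratum cohorts.
#' @param curve \code{"centile"} for \eqn{\hat y_k(age)} or \code{"rate"}
#'   for its derivative curve.
#' @param k percentile of the curve.
#' @param ages age grid on which bands are returned.
#' @param B number of bootstrap resamples.
#' @param probs lower/upper band probabilities.
#' @param seed integer seed.
#' @param units,span_years rate-curve options (see
#'   \code{\link{differentiate_centile}} and \code{\link{smooth_rate}}).
#' @return data frame (age, estimate, lower, upper) with attribute
#'   \code{n_failed}.
#' @export
bootstrap_bands <- function(cohort, column = "y0", spec = chart_spec(),
                            stratum = NULL, curve = c("centile", "rate"),
                            k = 0.5, ages, B = 500L, probs = c(0.25, 0.75),
                            seed = 1L, units = "absolute", span_years = 2.5) {
  curve <- match.arg(curve)
  if (B < 2L) stop("'B' must be at least 2")
  cohort <- as_longitudinal_cohort(cohort)
  keys <- stratum_key(cohort$sex, cohort$site)
  if (is.null(stratum)) {
    if (length(unique(keys)) != 1L)
      stop("cohort has multiple strata; specify 'stratum'")
    stratum <- unique(keys)
  }
  sub <- cohort[keys == stratum, , drop = FALSE]
  if (!nrow(sub)) stop(sprintf("unknown stratum '%s'", stratum))

  eval_curve <- function(tab) {
    m <- suppressWarnings(fit_centile_model(tab, column = column, spec = spec,
                                            min_n = 2L))
    if (!m$strata[[1L]]$converged) return(NULL)
    if (curve == "centile") {
      evaluate_centile(m, k = k, ages = ages, rule = "clamp")$value
    } else {
      dom <- m$strata[[1L]]$age_domain
      grid <- seq(dom[1], dom[2], by = 1 / 26)
      cc <- evaluate_centile(m, k = k, ages = grid, rule = "clamp")
      rc <- smooth_rate(differentiate_centile(cc, units = units),
                        span_years = span_years)
      stats::approx(rc$age, rc$rate, xout = ages, rule = 2)$y
    }
  }

  est <- eval_curve(sub)
  set.seed(seed)
  draws <- matrix(NA_real_, nrow = B, ncol = length(ages))
  failed <- 0L
  ids <- unique(sub$subject_id)
  for (b in seq_len(B)) {
    take <- sample(ids, length(ids), replace = TRUE)
    # subjects sampled multiple times appear multiple times
    rows <- unlist(lapply(take, function(id) which(sub$subject_id == id)))
    boot <- sub[rows, , drop = FALSE]
    boot$subject_id <- seq_len(nrow(boot))  # keep ids unique for validation
    v <- tryCatch(eval_curve(boot), error = function(e) NULL)
    if (is.null(v)) failed <- failed + 1L else draws[b, ] <- v
  }
  if (failed > 0.2 * B)
    warning(sprintf("%d of %d bootstrap refits failed", failed, B))
  ok <- stats::complete.cases(draws)
  qs <- apply(draws[ok, , drop = FALSE], 2, stats::quantile, probs = probs,
              names = FALSE)
  structure(data.frame(age = ages, estimate = est,
                       lower = qs[1, ], upper = qs[2, ]),
            n_failed = failed, class = c("bootstrap_bands", "data.frame"))
}

#' Serialize / restore a fitted centile model
#'
#' Writes the per-stratum basis ranges, coefficients, shape parameters and
#' fit metadata as a version-stamped JSON document, and reads it back.
#'
#' @param model a \code{centile_model}.
#' @param path file path.
#' @return \code{read_centile_model} returns the restored model.
#' @export
write_centile_model <- function(model, path) {
  stopifnot(inherits(model, "centile_model"))
  doc <- list(format = "chartrates-centile-model", version = 1L,
              column = model$column, age_column = model$age_column,
              spec = unclass(model$spec),
              subjects = model$subjects,
              strata = model$strata)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_centile_model
#' @export
read_centile_model <- function(path) {
  doc2 <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc2$format, "chartrates-centile-model"))
    stop("not a chartrates centile-model file")
  strata <- lapply(doc2$strata, function(f) {
    f$beta_mu <- as.numeric(unlist(f$beta_mu))
    f$beta_sigma <- as.numeric(unlist(f$beta_sigma))
    f$age_domain <- as.numeric(unlist(f$age_domain))
    for (nm in c("nu", "tau", "xmin", "xmax", "lambda_mu", "lambda_sigma",
                 "deviance"))
      f[[nm]] <- as.numeric(f[[nm]])
    for (nm in c("nbasis_mu", "nbasis_sigma", "iterations", "n"))
      f[[nm]] <- as.integer(f[[nm]])
    f$converged <- as.logical(f$converged)
    f
  })
  names(strata) <- names(doc2$strata)
  spec <- do.call(chart_spec, doc2$spec[c("nbasis_mu", "df_mu", "nbasis_sigma",
                                          "df_sigma", "penalty_order",
                                          "nu_start", "tau_start",
                                          "maxit", "tol")])
  structure(list(strata = strata, spec = spec, column = doc2$column,
                 age_column = doc2$age_column,
                 subjects = unlist(doc2$subjects)),
            class = "centile_model")
}
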