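# exact integral of the piecewise-linear interpolant of a rate curve,
# evaluated between arbitrary (possibly off-grid) ages; constant
# extrapolation at the grid edges within a configurable margin
rate_integral <- function(rate, from, to, clamp_margin = 1) {
  stopifnot(inherits(rate, "rate_curve"))
  a <- rate$age; r <- rate$rate; n <- length(a)
  lo <- a[1]; hi <- a[n]
  if (any(from < lo - clamp_margin) || any(to > hi + clamp_margin) ||
      any(to < lo - clamp_margin) || any(from > hi + clamp_margin))
    stop("ages fall outside the rate grid by more than the clamp margin (",
         clamp_margin, " y)")
  h <- a[2] - a[1]
  cum <- c(0, cumsum((r[-n] + r[-1]) / 2 * h))  # trapezoid at the knots
  C <- function(x) {
    below <- x < lo; above <- x > hi
    xx <- pmin(pmax(x, lo), hi)
    i <- pmin(findInterval(xx, a), n - 1L)
    rx <- r[i] + (r[i + 1L] - r[i]) * (xx - a[i]) / h
    val <- cum[i] + (xx - a[i]) * (r[i] + rx) / 2
    val[below] <- (x[below] - lo) * r[1]
    val[above] <- cum[n] + (x[above] - hi) * r[n]
    val
  }
  C(to) - C(from)
}

#' Predict a follow-up value by integrating a rate curve
#'
#' The chart-based prediction
#' \deqn{\hat y_1 = y_0 + \int_{age_0}^{age_1} \Delta^k(x)\, dx,}
#' evaluated by the trapezoidal rule at the rate curve's own grid spacing
#' (about two weeks), with linear interpolation of the rate at off-grid
#' endpoint ages. The rate curve must be in absolute units per year (not
#' percent).
#'
#' @param y0 baseline value(s).
#' @param age0,age1 baseline and follow-up age(s), \code{age1 > age0}.
#' @param rate an absolute-mode \code{\link{rate_curve}}.
#' @param clamp_margin how far (years) ages may fall outside the rate grid
#'   before an error; the overhang is integrated at the edge rate.
#' @return predicted follow-up value(s).
#' @export
predict_followup <- function(y0, age0, age1, rate, clamp_margin = 1) {
  stopifnot(inherits(rate, "rate_curve"))
  if (!identical(attr(rate, "units_mode"), "absolute"))
    stop("prediction requires an absolute-mode rate curve (units/year)")
  if (any(age1 <= age0)) stop("age1 must exceed age0")
  y0 + rate_integral(rate, age0, age1, clamp_margin = clamp_margin)
}

#' Chart-based and naive predictions for a whole cohort
#'
#' Predicts every subject's follow-up value by one of three methods:
#' \code{"median"} integrates the chart's median (k = 0.5 for everyone)
#' rate-of-change curve; \code{"individual"} first ranks each subject's
#' baseline on the chart (\code{\link{baseline_percentile}}) and integrates
#' that subject's own centile's rate curve; \code{"naive"} predicts no
#' change (\eqn{\hat y_1 = y_0}). Chart rate curves are differentiated at
#' \code{1/h_weeks}-week resolution in absolute units and smoothed with a
#' ±\code{span_years} moving average. The model should be fitted on
#' subjects disjoint from \code{cohort}; overlap triggers a warning unless
#' \code{allow_overlap}.
#'
#' @param cohort the test cohort.
#' @param model a fitted \code{\link{fit_centile_model}} (not needed for
#'   \code{"naive"}).
#' @param method prediction method.
#' @param k percentile used by the \code{"median"} method.
#' @param h grid spacing in years for differentiation (default 1/26, about
#'   two weeks).
#' @param span_years smoothing half-window (years).
#' @param allow_overlap suppress the train/test overlap warning.
#' @return data frame of class \code{prediction_records}: subject_id,
#'   method, k, age0, age1, y0, y1_pred, y1_obs, ae, ae_norm (absolute
#'   error over baseline value), clamped.
#' @export
predict_cohort <- function(cohort, model = NULL,
                           method = c("median", "individual", "naive"),
                           k = 0.5, h = 1 / 26, span_years = 2.5,
                           allow_overlap = FALSE) {
  method <- match.arg(method)
  cohort <- as_longitudinal_cohort(cohort)
  if (method == "naive") {
    recs <- data.frame(subject_id = cohort$subject_id, method = "naive",
                       k = NA_real_, age0 = cohort$age0, age1 = cohort$age1,
                       y0 = cohort$y0, y1_pred = cohort$y0,
                       y1_obs = cohort$y1, clamped = FALSE)
  } else {
    stopifnot(inherits(model, "centile_model"))
    if (!allow_overlap && length(intersect(model$subjects, cohort$subject_id)))
      warning("cohort overlaps the model's training subjects; ",
              "predictions are not out-of-sample")
    keys <- stratum_key(cohort$sex, cohort$site)
    unknown <- setdiff(unique(keys), names(model$strata))
    if (length(unknown))
      stop("cohort strata missing from the model: ",
           paste(unknown, collapse = ", "))
    y1_pred <- rep(NA_real_, nrow(cohort))
    kcol <- rep(k, nrow(cohort))
    clamped <- rep(FALSE, nrow(cohort))
    for (key in unique(keys)) {
      idx <- which(keys == key)
      fit <- model$strata[[key]]
      dom <- fit$age_domain
      grid <- seq(dom[1], dom[2], by = h)
      clamped[idx] <- cohort$age0[idx] < dom[1] | cohort$age1[idx] > dom[2]
      if (method == "median") {
        cc <- evaluate_centile(model, k = k, ages = grid, stratum = key,
                               rule = "clamp")
        rc <- smooth_rate(differentiate_centile(cc, units = "absolute"),
                          span_years = span_years)
        y1_pred[idx] <- predict_followup(cohort$y0[idx], cohort$age0[idx],
                                         cohort$age1[idx], rc,
                                         clamp_margin = Inf)
      } else {
        ki <- baseline_percentile(model, cohort$y0[idx], cohort$age0[idx],
                                  stratum = key)
        kcol[idx] <- ki
        pa <- params_at_age(fit, grid, rule = "clamp")
        for (j in seq_along(idx)) {
          vals <- qbct(ki[j], pa$mu, pa$sigma, pa$nu, pa$tau)
          cc <- structure(data.frame(age = grid, value = vals), k = ki[j],
                          class = c("centile_curve", "data.frame"))
          rc <- smooth_rate(differentiate_centile(cc, units = "absolute"),
                            span_years = span_years)
          y1_pred[idx[j]] <- predict_followup(cohort$y0[idx[j]],
                                              cohort$age0[idx[j]],
                                              cohort$age1[idx[j]], rc,
                                              clamp_margin = Inf)
        }
      }
    }
    recs <- data.frame(subject_id = cohort$subject_id,
                       method = if (method == "median") "median-centile"
                                else "individual-centile",
                       k = kcol, age0 = cohort$age0, age1 = cohort$age1,
                       y0 = cohort$y0, y1_pred = y1_pred,
                       y1_obs = cohort$y1, clamped = clamped)
  }
  recs$ae <- abs(recs$y1_pred - recs$y1_obs)
  recs$ae_norm <- recs$ae / recs$y0
  structure(recs, class = c("prediction_records", "data.frame"))
}

#' Mean absolute error of a prediction-record table
#'
#' \eqn{MAE = \frac{1}{N}\sum_i |\hat y_{1,i} - y_{1,i}|}.
#'
#' @param records a \code{prediction_records} table.
#' @return the MAE (phenotype units).
#' @export
mean_absolute_error <- function(records) {
  stopifnot(is.data.frame(records), "ae" %in% names(records))
  if (!nrow(records)) stop("no prediction records")
  mean(records$ae)
}

#' Paired comparison of two prediction methods
#'
#' Paired two-sided t-test on per-subject absolute-error differences
#' (method A minus method B), with the paired Cohen's d
#' (mean difference over SD of differences) and the percent reduction in
#' MAE, \code{(MAE_B - MAE_A) / MAE_B * 100}. Records are matched by
#' subject id. Zero-variance differences make d undefined (returned as NA,
#' with p = 1 for exact ties).
#'
#' @param records_a,records_b \code{prediction_records} for the same
#'   subjects.
#' @param label optional contrast label.
#' @return object of class \code{comparison_result}: list(statistic, df, p,
#'   p_fdr, cohens_d, n, mae_a, mae_b, percent_reduction, label).
#' @export
compare_mae <- function(records_a, records_b, label = NULL) {
  m <- merge(records_a[, c("subject_id", "ae")],
             records_b[, c("subject_id", "ae")],
             by = "subject_id", suffixes = c("_a", "_b"))
  if (!nrow(m)) stop("no common subjects between the two record tables")
  d <- m$ae_a - m$ae_b
  mae_a <- mean(m$ae_a); mae_b <- mean(m$ae_b)
  if (is.null(label))
    label <- paste(records_a$method[1], "vs", records_b$method[1])
  comparison_from_diffs(d, n = nrow(m), label = label,
                        extra = list(mae_a = mae_a, mae_b = mae_b,
                                     percent_reduction =
                                       (mae_b - mae_a) / mae_b * 100))
}

comparison_from_diffs <- function(d, n, label, extra = list()) {
  sdd <- stats::sd(d)
  if (n < 2 || !is.finite(sdd) || sdd == 0) {
    tt <- list(statistic = if (all(d == 0)) 0 else NA_real_,
               parameter = n - 1, p.value = if (all(d == 0)) 1 else NA_real_)
    cd <- NA_real_
  } else {
    ht <- stats::t.test(d)
    tt <- list(statistic = unname(ht$statistic),
               parameter = unname(ht$parameter), p.value = ht$p.value)
    cd <- mean(d) / sdd
  }
  structure(c(list(statistic = tt$statistic, df = tt$parameter,
                   p = tt$p.value, p_fdr = NA_real_, cohens_d = cd,
                   mean_difference = mean(d), n = n, label = label),
              extra),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: t = %.3f, p = %.3g%s, d = %.3f, n = %d\n", x$label,
              x$statistic, x$p,
              if (is.finite(x$p_fdr)) sprintf(" (p_FDR = %.3g)", x$p_fdr)
              else "",
              x$cohens_d, x$n))
  if (!is.null(x$percent_reduction))
    cat(sprintf("  MAE %.4g vs %.4g (%.1f%% reduction)\n", x$mae_a, x$mae_b,
                x$percent_reduction))
  invisible(x)
}

#' Compare observed longitudinal rates against a cross-sectional rate curve
#'
#' For each subject, the difference between the observed annualized rate
#' and the cross-sectional chart-derived rate evaluated at the subject's
#' mid-age (absolute units); a paired two-sided t-test and paired Cohen's d
#' summarize whether cross-sectional and longitudinal rate estimates
#' diverge. FDR across phenotypes is applied by the caller.
#'
#' @param cross an absolute-mode \code{\link{rate_curve}} covering the
#'   rates' mid-ages.
#' @param rates a \code{rate_sample} from \code{\link{annualized_rates}}.
#' @param label optional contrast label.
#' @return a \code{comparison_result}; positive t means longitudinal rates
#'   exceed (are less negative than) the cross-sectional curve.
#' @export
compare_rate_estimates <- function(cross, rates,
                                   label = "longitudinal vs cross-sectional rate") {
  stopifnot(inherits(cross, "rate_curve"), inherits(rates, "rate_sample"))
  if (!identical(attr(cross, "units_mode"), "absolute"))
    stop("'cross' must be in absolute units")
  curve_at <- stats::approx(cross$age, cross$rate, xout = rates$mid_age,
                            rule = 2)$y
  comparison_from_diffs(rates$rate - curve_at, n = nrow(rates), label = label)
}

#' Age-randomization permutation null for chart-based prediction
#'
#' Tests whether chart-based predictions actually exploit age: each
#' permutation adds an independent Uniform(-shift, +shift)-year offset to
#' every subject's ages (the same offset to baseline and follow-up, so the
#' interscan interval is preserved; offsets are truncated so both ages stay
#' within the rate grid, and affected subjects are counted), recomputes the
#' median-centile predictions, and records the null MAE. The p-value uses
#' the add-one convention \code{p = (1 + #\{null MAE <= observed\}) /
#' (n_perm + 1)}. Deterministic given \code{seed}.
#'
#' @param cohort test cohort (disjoint from the model's training subjects).
#' @param model a fitted \code{centile_model}, or an absolute-mode
#'   \code{\link{rate_curve}} (applied to every stratum) to test a
#'   prespecified rate chart directly.
#' @param n_perm number of permutations (the reference analysis uses 1000).
#' @param shift half-width of the uniform age offset (years; default ±5).
#' @param seed integer seed.
#' @param k,h,span_years passed to the median-centile prediction.
#' @return list: observed_mae, null_mae (length n_perm), p, n_clamped.
#' @export
permutation_null <- function(cohort, model, n_perm = 1000L, shift = 5,
                             seed = 1L, k = 0.5, h = 1 / 26,
                             span_years = 2.5) {
  if (n_perm < 1) stop("'n_perm' must be a positive integer")
  cohort <- as_longitudinal_cohort(cohort)
  keys <- stratum_key(cohort$sex, cohort$site)
  if (inherits(model, "rate_curve")) {
    if (!identical(attr(model, "units_mode"), "absolute"))
      stop("a rate-curve null requires absolute units")
    curves <- lapply(stats::setNames(unique(keys), unique(keys)),
                     function(key) model)
  } else {
    stopifnot(inherits(model, "centile_model"))
    unknown <- setdiff(unique(keys), names(model$strata))
    if (length(unknown))
      stop("cohort strata missing from the model: ",
           paste(unknown, collapse = ", "))
    # the median rate curve per stratum is fixed; only integration limits move
    curves <- lapply(stats::setNames(names(model$strata),
                                     names(model$strata)), function(key) {
      dom <- model$strata[[key]]$age_domain
      grid <- seq(dom[1], dom[2], by = h)
      cc <- evaluate_centile(model, k = k, ages = grid, stratum = key,
                             rule = "clamp")
      smooth_rate(differentiate_centile(cc, units = "absolute"),
                  span_years = span_years)
    })
  }

  mae_for <- function(delta) {
    ae <- numeric(nrow(cohort))
    for (key in unique(keys)) {
      idx <- which(keys == key)
      rc <- curves[[key]]
      a0 <- cohort$age0[idx] + delta[idx]
      a1 <- cohort$age1[idx] + delta[idx]
      pred <- cohort$y0[idx] + rate_integral(rc, a0, a1, clamp_margin = Inf)
      ae[idx] <- abs(pred - cohort$y1[idx])
    }
    mean(ae)
  }

  observed <- mae_for(rep(0, nrow(cohort)))

  set.seed(seed)
  n_clamped <- 0L
  null_mae <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    delta <- stats::runif(nrow(cohort), -shift, shift)
    # keep both occasions inside the rate grid, preserving the interval
    for (key in unique(keys)) {
      idx <- which(keys == key)
      dom <- range(curves[[key]]$age)
      lo <- dom[1] - cohort$age0[idx]
      hi <- dom[2] - cohort$age1[idx]
      clip <- pmin(pmax(delta[idx], lo), hi)
      n_clamped <- n_clamped + sum(abs(clip - delta[idx]) > 1e-12)
      delta[idx] <- clip
    }
    null_mae[b] <- mae_for(delta)
  }
  # tolerance absorbs floating-point jitter so exact ties count as ties
  p <- (1 + sum(null_mae <= observed * (1 + 1e-12) + 1e-12)) / (n_perm + 1)
  list(observed_mae = observed, null_mae = null_mae, p = p,
       n_clamped = n_clamped)
}

#' Fraction of subjects with upward observed slopes
#'
#' Proportion of annualized rates strictly greater than zero (exact zeros
#' count as not upward).
#'
#' @param rates a \code{rate_sample} (or any data frame with a \code{rate}
#'   column).
#' @return proportion in [0, 1].
#' @export
upward_fraction <- function(rates) {
  stopifnot(is.data.frame(rates), "rate" %in% names(rates))
  if (!nrow(rates)) stop("empty rate table")
  mean(rates$rate > 0)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate across a
#' family of tests (monotone, capped at 1).
#'
#' @param pvalues vector of p-values in [0, 1].
#' @return adjusted p-values.
#' @export
fdr_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}
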