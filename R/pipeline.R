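#' End-to-end pipeline configuration
#'
#' Bundles every knob of the analysis: the input (a cohort CSV path or a
#' \code{\link{simulation_config}}), the centile-fit structure, the
#' differentiation grid and smoothing span, the percentile set evaluated
#' for the charts, bootstrap and permutation settings, the train/test
#' split, and one root seed from which the stage substreams (simulate,
#' split, bootstrap, permute) are derived so each stage is independently
#' reproducible.
#'
#' @param input path to a cohort CSV, or NULL to simulate.
#' @param simulation a \code{\link{simulation_config}} used when
#'   \code{input} is NULL.
#' @param spec a \code{\link{chart_spec}}.
#' @param percentiles centile set evaluated for the charts.
#' @param h differentiation grid spacing (years; default about two weeks).
#' @param span_years moving-average half-window (years).
#' @param bootstrap_B bootstrap resamples for the median-centile band
#'   (0 disables the band stage).
#' @param n_perm,perm_shift permutation-null settings (count, ±years).
#' @param train_fraction subject-level training fraction.
#' @param seed root integer seed.
#' @param outdir output directory (created if needed).
#' @return an object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(input = NULL, simulation = simulation_config(),
                            spec = chart_spec(),
                            percentiles = c(0.02, 0.16, 0.5, 0.84, 0.98),
                            h = 1 / 26, span_years = 2.5, bootstrap_B = 0L,
                            n_perm = 200L, perm_shift = 5,
                            train_fraction = 0.5, seed = 1L,
                            outdir = tempfile("chartrates_run_")) {
  stopifnot(is.null(input) || file.exists(input),
            inherits(spec, "chart_spec"),
            all(percentiles > 0 & percentiles < 1),
            h > 0, train_fraction > 0, train_fraction < 1, n_perm >= 0,
            seed == as.integer(seed), abs(seed) < 2^31 - 10)
  structure(list(input = input, simulation = simulation, spec = spec,
                 percentiles = percentiles, h = h, span_years = span_years,
                 bootstrap_B = as.integer(bootstrap_B),
                 n_perm = as.integer(n_perm), perm_shift = perm_shift,
                 train_fraction = train_fraction, seed = as.integer(seed),
                 outdir = outdir),
            class = "pipeline_config")
}

# small stable content hash (polynomial rolling hash over the deparsed object)
config_hash <- function(x) {
  s <- paste(deparse(x, control = "exact"), collapse = "\n")
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full cross-vs-longitudinal analysis pipeline
#'
#' Executes, in order: (optional) cohort simulation; subject-level
#' train/test split; cross-sectional BCT centile chart fit on the training
#' baselines; numerical differentiation and moving-average smoothing of
#' the chart percentiles; per-subject annualized longitudinal rates and the
#' longitudinal rate chart; the cross-vs-longitudinal percent-difference
#' summary; naive, median-centile and individual-centile follow-up
#' predictions on the held-out half; paired MAE comparisons and the
#' age-randomization permutation null; and error-covariate associations.
#' Every stage writes its tables under \code{config$outdir}, a manifest
#' records the seed and config hash, and a rerun with the same config is
#' bit-identical. A stage failure leaves earlier outputs in place and names
#' the failed stage.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return (invisibly) a list with the cohort, fitted models, record tables
#'   and the summary, as written to disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(config$outdir, "log.txt")
  loglines <- character()
  say <- function(fmt, ...) {
    loglines <<- c(loglines, sprintf(fmt, ...))
    writeLines(loglines, logfile)
  }
  stage <- function(name, expr) {
    say("stage %s: start", name)
    out <- tryCatch(expr, error = function(e) {
      say("stage %s: FAILED (%s)", name, conditionMessage(e))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    say("stage %s: done", name)
    out
  }
  seeds <- list(simulate = config$seed, split = config$seed + 1L,
                bootstrap = config$seed + 2L, permute = config$seed + 3L)
  say("chartrates pipeline; root seed %d; config hash %s; R %s",
      config$seed, config_hash(unclass(config)), getRversion())
  artifacts <- character()
  put <- function(name) {
    artifacts <<- c(artifacts, name)
    file.path(config$outdir, name)
  }

  cohort <- stage("input", {
    if (!is.null(config$input)) load_cohort(config$input) else {
      sim <- config$simulation
      sim$seed <- seeds$simulate
      simulate_cohort(sim)
    }
  })
  write_cohort(cohort, put("cohort.csv"))
  analyzed <- cohort[cohort$retained %||% TRUE, , drop = FALSE]

  halves <- stage("split", split_cohort(analyzed,
                                        fraction = config$train_fraction,
                                        seed = seeds$split))
  say("split: %d train / %d test subjects", nrow(halves$train),
      nrow(halves$test))

  model <- stage("fit_chart",
                 fit_centile_model(halves$train, column = "y0",
                                   spec = config$spec))
  write_centile_model(model, put("centile_model.json"))

  curves <- stage("centile_curves", {
    out <- list()
    for (key in names(model$strata)) {
      dom <- model$strata[[key]]$age_domain
      grid <- seq(dom[1], dom[2], by = config$h)
      for (k in config$percentiles) {
        cc <- evaluate_centile(model, k = k, ages = grid, stratum = key)
        out[[paste(key, k)]] <- data.frame(stratum = key, k = k,
                                           age = cc$age, value = cc$value)
      }
    }
    do.call(rbind, out)
  })
  utils::write.csv(curves, put("centile_curves.csv"), row.names = FALSE)

  cross_rates <- stage("differentiate", {
    lapply(stats::setNames(names(model$strata), names(model$strata)),
           function(key) {
      dom <- model$strata[[key]]$age_domain
      grid <- seq(dom[1], dom[2], by = config$h)
      cc <- evaluate_centile(model, k = 0.5, ages = grid, stratum = key)
      list(absolute = smooth_rate(differentiate_centile(cc, "absolute"),
                                  config$span_years),
           percent = smooth_rate(differentiate_centile(cc, "percent"),
                                 config$span_years))
    })
  })

  rates <- stage("annualized_rates", annualized_rates(halves$train))
  chart <- stage("rate_chart", fit_rate_chart(rates))
  long_rates <- lapply(stats::setNames(names(chart$strata),
                                       names(chart$strata)), function(key) {
    dom <- chart$strata[[key]]$age_domain
    evaluate_rate_chart(chart, seq(dom[1], dom[2], by = config$h),
                        stratum = key)
  })
  rate_tab <- do.call(rbind, c(
    lapply(names(cross_rates), function(key)
      data.frame(stratum = key, provenance = "cross", units = "absolute",
                 age = cross_rates[[key]]$absolute$age,
                 rate = cross_rates[[key]]$absolute$rate)),
    lapply(names(long_rates), function(key)
      data.frame(stratum = key, provenance = "longitudinal",
                 units = "absolute", age = long_rates[[key]]$age,
                 rate = long_rates[[key]]$rate))))
  utils::write.csv(rate_tab, put("rate_curves.csv"), row.names = FALSE)

  pd <- stage("percent_difference", {
    common <- intersect(names(cross_rates), names(long_rates))
    lapply(stats::setNames(common, common), function(key)
      percent_difference(cross_rates[[key]]$absolute, long_rates[[key]],
                         boundary_margin = config$span_years))
  })
  jsonlite::write_json(
    lapply(pd, function(x) x[c("max_percent_difference", "age_at_max")]),
    put("percent_difference.json"), auto_unbox = TRUE, digits = NA)

  bands <- NULL
  if (config$bootstrap_B >= 2) {
    bands <- stage("bootstrap_bands", {
      out <- list()
      for (key in names(model$strata)) {
        dom <- model$strata[[key]]$age_domain
        grid <- seq(dom[1], dom[2], length.out = 41)
        tr <- halves$train
        kk <- stratum_key(tr$sex, tr$site)
        bb <- bootstrap_bands(tr[kk == key, , drop = FALSE],
                              spec = config$spec, stratum = key,
                              curve = "centile", k = 0.5, ages = grid,
                              B = config$bootstrap_B, seed = seeds$bootstrap)
        out[[key]] <- data.frame(stratum = key, bb)
      }
      do.call(rbind, out)
    })
    utils::write.csv(bands, put("centile_bands.csv"), row.names = FALSE)
  }

  preds <- stage("predict", {
    list(naive = predict_cohort(halves$test, method = "naive"),
         median = predict_cohort(halves$test, model, method = "median",
                                 h = config$h,
                                 span_years = config$span_years),
         individual = predict_cohort(halves$test, model,
                                     method = "individual", h = config$h,
                                     span_years = config$span_years))
  })
  utils::write.csv(do.call(rbind, preds), put("predictions.csv"),
                   row.names = FALSE)

  comparisons <- stage("compare", {
    cmp <- list(
      median_vs_naive = compare_mae(preds$median, preds$naive),
      individual_vs_naive = compare_mae(preds$individual, preds$naive),
      individual_vs_median = compare_mae(preds$individual, preds$median),
      rates = {
        test_rates <- annualized_rates(halves$test)
        kk <- stratum_key(test_rates$sex, test_rates$site)
        diffs <- unlist(lapply(unique(kk), function(key) {
          rc <- cross_rates[[key]]$absolute
          sub <- test_rates[kk == key, , drop = FALSE]
          sub$rate - stats::approx(rc$age, rc$rate, xout = sub$mid_age,
                                   rule = 2)$y
        }))
        comparison_from_diffs(diffs, n = length(diffs),
                              label = "longitudinal vs cross-sectional rate")
      })
    ps <- vapply(cmp, function(x) x$p, numeric(1))
    adj <- fdr_adjust(ps)
    for (i in seq_along(cmp)) cmp[[i]]$p_fdr <- adj[i]
    cmp
  })
  jsonlite::write_json(lapply(comparisons, unclass), put("comparisons.json"),
                       auto_unbox = TRUE, digits = NA)

  perm <- stage("permutation_null", {
    if (config$n_perm >= 1)
      permutation_null(halves$test, model, n_perm = config$n_perm,
                       shift = config$perm_shift, seed = seeds$permute,
                       h = config$h, span_years = config$span_years)
    else NULL
  })
  if (!is.null(perm))
    jsonlite::write_json(perm[c("observed_mae", "p", "n_clamped")],
                         put("permutation.json"), auto_unbox = TRUE,
                         digits = NA)

  correlates <- stage("error_correlates", error_correlates(preds$median))
  utils::write.csv(correlates, put("correlates.csv"), row.names = FALSE)

  summary <- stage("summary", {
    test_rates <- annualized_rates(halves$test)
    list(seed = config$seed,
         n_subjects = nrow(cohort),
         n_train = nrow(halves$train), n_test = nrow(halves$test),
         strata = names(model$strata),
         max_percent_difference =
           vapply(pd, function(x) x$max_percent_difference, numeric(1)),
         age_at_max_percent_difference =
           vapply(pd, function(x) x$age_at_max, numeric(1)),
         mae = list(naive = mean_absolute_error(preds$naive),
                    median_centile = mean_absolute_error(preds$median),
                    individual_centile =
                      mean_absolute_error(preds$individual)),
         percent_reduction_median_vs_naive =
           comparisons$median_vs_naive$percent_reduction,
         rate_comparison = list(t = comparisons$rates$statistic,
                                p_fdr = comparisons$rates$p_fdr,
                                cohens_d = comparisons$rates$cohens_d),
         upward_fraction = upward_fraction(test_rates),
         permutation_p = if (!is.null(perm)) perm$p else NULL)
  })
  jsonlite::write_json(summary, put("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  manifest <- list(format = "chartrates-manifest", version = 1L,
                   seed = config$seed, substreams = seeds,
                   config_hash = config_hash(unclass(config)),
                   artifacts = c(artifacts, "log.txt", "manifest.json"))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("pipeline complete: %d artifacts in %s", length(manifest$artifacts),
      config$outdir)
  invisible(list(cohort = cohort, split = halves, model = model,
                 cross_rates = cross_rates, long_rates = long_rates,
                 rate_chart = chart, percent_difference = pd, bands = bands,
                 predictions = preds, comparisons = comparisons,
                 permutation = perm, correlates = correlates,
                 summary = summary, outdir = config$outdir))
}
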