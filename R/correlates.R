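#' Associations between prediction errors and covariates
#'
#' Relates the normalized absolute error (AE over the subject's baseline
#' value) to candidate sources of nonage-related variability. Confound
#' columns are standardized and summarized by PCA into \code{n_pcs}
#' component scores, which join the tested covariates. Numeric covariates
#' are tested by Pearson correlation with the normalized AE (reporting r
#' and the variance explained r^2); binary covariates by a two-sample
#' t-test (with the point-biserial r^2 alongside). Two derived covariates
#' are always tested when computable from the records: the direction of
#' observed change (upward vs downward) and the interscan interval.
#' p-values are FDR-adjusted (Benjamini-Hochberg) across every covariate
#' tested. Constant covariates are skipped with a note.
#'
#' @param records a \code{prediction_records} table.
#' @param covariates optional data frame with \code{subject_id} plus
#'   numeric or binary covariate columns.
#' @param confounds optional data frame with \code{subject_id} plus numeric
#'   confound columns to be PCA-summarized.
#' @param n_pcs number of principal components retained from the confounds.
#' @return data frame: covariate, type (numeric/binary), n, estimate (r or
#'   group mean difference), r2, statistic, p, p_fdr, note.
#' @export
error_correlates <- function(records, covariates = NULL, confounds = NULL,
                             n_pcs = 3L) {
  stopifnot(is.data.frame(records),
            all(c("subject_id", "ae_norm") %in% names(records)))
  tab <- records[, intersect(c("subject_id", "ae_norm", "age0", "age1",
                               "y0", "y1_obs"), names(records))]

  covs <- list()
  if (all(c("y0", "y1_obs") %in% names(tab)))
    covs$direction_upward <- as.numeric(tab$y1_obs > tab$y0)
  if (all(c("age0", "age1") %in% names(tab)))
    covs$interscan_interval <- tab$age1 - tab$age0

  if (!is.null(covariates)) {
    stopifnot("subject_id" %in% names(covariates))
    m <- match(tab$subject_id, covariates$subject_id)
    for (nm in setdiff(names(covariates), "subject_id"))
      covs[[nm]] <- covariates[[nm]][m]
  }
  if (!is.null(confounds)) {
    stopifnot("subject_id" %in% names(confounds))
    m <- match(tab$subject_id, confounds$subject_id)
    X <- as.matrix(confounds[m, setdiff(names(confounds), "subject_id"),
                             drop = FALSE])
    keep <- apply(X, 2, function(v) stats::sd(v, na.rm = TRUE) > 0)
    X <- scale(X[, keep, drop = FALSE])
    npc <- min(n_pcs, ncol(X))
    if (npc >= 1) {
      pc <- stats::prcomp(X, center = FALSE, scale. = FALSE)
      for (j in seq_len(npc)) covs[[paste0("confound_PC", j)]] <- pc$x[, j]
    }
  }
  if (!length(covs)) stop("no covariates to test")

  rows <- lapply(names(covs), function(nm) {
    v <- covs[[nm]]
    ok <- is.finite(v) & is.finite(tab$ae_norm)
    v <- v[ok]; ae <- tab$ae_norm[ok]
    base <- data.frame(covariate = nm, type = NA_character_,
                       n = length(v), estimate = NA_real_, r2 = NA_real_,
                       statistic = NA_real_, p = NA_real_, p_fdr = NA_real_,
                       note = "")
    uv <- unique(v)
    if (length(uv) < 2L) {
      base$note <- "constant covariate; skipped"
      return(base)
    }
    if (is.logical(covs[[nm]]) || length(uv) == 2L) {
      g <- v == max(uv)
      ht <- stats::t.test(ae[g], ae[!g])
      base$type <- "binary"
      base$estimate <- mean(ae[g]) - mean(ae[!g])
      base$r2 <- stats::cor(ae, as.numeric(g))^2
      base$statistic <- unname(ht$statistic)
      base$p <- ht$p.value
    } else {
      ht <- stats::cor.test(v, ae)
      base$type <- "numeric"
      base$estimate <- unname(ht$estimate)
      base$r2 <- unname(ht$estimate)^2
      base$statistic <- unname(ht$statistic)
      base$p <- ht$p.value
    }
    base
  })
  out <- do.call(rbind, rows)
  tested <- !is.na(out$p)
  out$p_fdr[tested] <- fdr_adjust(out$p[tested])
  out
}
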