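#' Validate a two-occasion longitudinal cohort table
#'
#' The pipeline's universal input: one row per subject with a baseline and a
#' follow-up measurement of one positive-valued phenotype. Required columns
#' are \code{subject_id}, \code{sex}, \code{site}, \code{age0}, \code{age1},
#' \code{y0}, \code{y1}; any further columns (covariates, simulation truth)
#' are carried along. Enforced invariants: unique subject ids,
#' \code{age1 > age0}, and \code{y0, y1 > 0} for every record.
#'
#' @param x a data frame.
#' @return the validated data frame with class \code{longitudinal_cohort}.
#' @export
as_longitudinal_cohort <- function(x) {
  if (inherits(x, "longitudinal_cohort")) return(x)
  stopifnot(is.data.frame(x))
  required <- c("subject_id", "sex", "site", "age0", "age1", "y0", "y1")
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop("missing required columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(x$subject_id))
    stop("subject_id values must be unique")
  if (any(x$age1 - x$age0 <= 0))
    stop("age1 must exceed age0 for every record")
  if (any(x$y0 <= 0) || any(x$y1 <= 0))
    stop("phenotype values must be strictly positive")
  class(x) <- unique(c("longitudinal_cohort", class(x)))
  x
}

#' Read a cohort table from CSV/TSV
#'
#' Reads a delimited file (delimiter sniffed from the header line unless
#' given), types the required columns, and validates the cohort invariants.
#' In strict mode any violation aborts with the offending row numbers; in
#' lenient mode violating rows are dropped and reported via a message.
#'
#' @param path file path.
#' @param strict abort on invalid rows (default) or drop them.
#' @param sep field delimiter; \code{NULL} to sniff comma vs tab.
#' @return a \code{longitudinal_cohort}.
#' @export
load_cohort <- function(path, strict = TRUE, sep = NULL) {
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("subject_id", "sex", "site", "age0", "age1", "y0", "y1")
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop("missing required columns: ", paste(missing, collapse = ", "),
         " (found: ", paste(names(x), collapse = ", "), ")")
  for (cc in c("age0", "age1", "y0", "y1")) x[[cc]] <- as.numeric(x[[cc]])
  bad <- which(!is.finite(x$age0) | !is.finite(x$age1) |
                 !is.finite(x$y0) | !is.finite(x$y1) |
                 x$age1 - x$age0 <= 0 | x$y0 <= 0 | x$y1 <= 0 |
                 duplicated(x$subject_id))
  if (length(bad)) {
    msg <- paste0("invalid cohort rows: ", paste(bad, collapse = ", "))
    if (strict) stop(msg) else {
      message(msg, " (dropped)")
      x <- x[-bad, , drop = FALSE]
    }
  }
  as_longitudinal_cohort(x)
}

#' Write a cohort table to CSV
#'
#' @param cohort a \code{longitudinal_cohort}.
#' @param path output file path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' Split a cohort into training and test halves
#'
#' Seeded subject-level split, stratified by sex-by-site cell so every
#' stratum is represented on both sides. Charts are fitted on the training
#' half and predictions evaluated on held-out subjects.
#'
#' @param cohort a \code{longitudinal_cohort}.
#' @param fraction training fraction.
#' @param seed integer seed.
#' @return list with elements \code{train} and \code{test}.
#' @export
split_cohort <- function(cohort, fraction = 0.5, seed = 1L) {
  cohort <- as_longitudinal_cohort(cohort)
  stopifnot(fraction > 0, fraction < 1)
  set.seed(seed)
  keys <- stratum_key(cohort$sex, cohort$site)
  train_idx <- unlist(lapply(split(seq_len(nrow(cohort)), keys), function(ix) {
    n_tr <- max(1L, round(length(ix) * fraction))
    sample(ix, n_tr)
  }), use.names = FALSE)
  list(train = as_longitudinal_cohort(cohort[sort(train_idx), , drop = FALSE]),
       test = as_longitudinal_cohort(cohort[-sort(train_idx), , drop = FALSE]))
}
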