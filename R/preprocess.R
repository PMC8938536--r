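#' Two-step normalization: internal standard, then fresh weight
#'
#' Divides every peak area by the internal-standard peak of the same sample
#' and then by the sample's fresh weight, yielding abundance per mg fresh
#' weight. The standard row is removed from the output. Per-sample detector
#' gain cancels exactly because it scales the standard peak and every
#' metabolite peak alike. Missing values stay missing; no further
#' statistical normalization is applied.
#'
#' @param peaks `abundance_matrix` in `raw_peak` state containing the
#'   standard row, positive in every sample.
#' @param meta sample metadata with positive `fresh_weight_mg` for every
#'   matrix sample.
#' @param standard_id internal-standard row id; defaults to the one recorded
#'   on the matrix.
#' @return `abundance_matrix` in `normalized` state, standard row removed.
#' @export
normalize_abundance <- function(peaks, meta, standard_id = peaks$standard_id) {
  stopifnot(inherits(peaks, "abundance_matrix"))
  if (peaks$state != "raw_peak") stop("normalize expects a raw_peak matrix")
  if (is.null(standard_id)) stop("standard_id must be given")
  if (!standard_id %in% rownames(peaks$values)) {
    stop("internal standard '", standard_id, "' not found in matrix")
  }
  validate_sample_meta(meta)
  sids <- sample_ids(peaks)
  idx <- match(sids, meta$sample_id)
  if (anyNA(idx)) {
    stop("metadata missing for samples: ",
         paste(utils::head(sids[is.na(idx)], 5), collapse = ", "))
  }
  fw <- meta$fresh_weight_mg[idx]
  if (anyNA(fw) || any(fw <= 0)) {
    stop("fresh_weight_mg required and positive for all samples; offending: ",
         paste(utils::head(sids[is.na(fw) | fw <= 0], 5), collapse = ", "))
  }
  std <- peaks$values[standard_id, ]
  bad <- is.na(std) | std <= 0
  if (any(bad)) {
    stop("internal standard peak missing or non-positive in sample(s): ",
         paste(utils::head(sids[bad], 5), collapse = ", "))
  }
  vals <- peaks$values[setdiff(rownames(peaks$values), standard_id), ,
                       drop = FALSE]
  # sequential division: first by the standard peak, then by fresh weight
  out <- sweep(sweep(vals, 2, std, `/`), 2, fw, `/`)
  abundance_matrix(out, state = "normalized")
}

#' Log-transform a normalized abundance matrix
#'
#' Element-wise logarithm in the configured base; missing values are
#' preserved. Zero or negative values are an error (no pseudo-count is ever
#' added silently).
#'
#' @param abund `abundance_matrix` in `normalized` state.
#' @param base `"e"` (default), `"10"` or `"2"`.
#' @return `abundance_matrix` in `log` state.
#' @export
log_transform <- function(abund, base = c("e", "10", "2")) {
  stopifnot(inherits(abund, "abundance_matrix"))
  base <- match.arg(as.character(base), c("e", "10", "2"))
  if (abund$state != "normalized") {
    stop("log_transform expects a normalized matrix")
  }
  v <- abund$values
  bad <- which(!is.na(v) & v <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    cells <- apply(utils::head(bad, 10), 1, function(b) {
      sprintf("(%s, %s)", rownames(v)[b[1]], colnames(v)[b[2]])
    })
    stop("non-positive values cannot be log-transformed: ",
         paste(cells, collapse = ", "),
         if (nrow(bad) > 10) sprintf(" and %d more", nrow(bad) - 10) else "")
  }
  out <- switch(base, e = log(v), `10` = log10(v), `2` = log2(v))
  abundance_matrix(out, state = "log", log_base = base)
}

#' Classify per-sample log-medians against dataset quartiles
#'
#' The QC rule: a sample is an outlier when its log-median lies strictly
#' above the dataset's third quartile or strictly below its first quartile
#' (a median exactly at Q1/Q3 is kept). Quartiles are computed over all
#' pooled log-transformed measurements.
#'
#' @param medians numeric vector of per-sample log-medians.
#' @param q1,q3 dataset first and third quartile of all pooled log values.
#' @return character vector: `"above_q3"`, `"below_q1"` or `"ok"`.
#' @export
classify_sample_medians <- function(medians, q1, q3) {
  if (q1 > q3) stop("q1 must not exceed q3")
  ifelse(medians > q3, "above_q3",
         ifelse(medians < q1, "below_q1", "ok"))
}

#' Flag outlier samples by the pooled-quartile median rule
#'
#' Computes Q1/Q3 (linear-interpolation quantiles) over all pooled
#' non-missing log values, the per-sample median over each sample's
#' non-missing values, and flags samples whose median falls strictly outside
#' \[Q1, Q3\].
#'
#' @param logged `abundance_matrix` in `log` state with >= 2 samples.
#' @return object of class `outlier_report`: per-sample medians, dataset
#'   median/Q1/Q3, and the flagged samples with direction.
#' @export
flag_outlier_samples <- function(logged) {
  stopifnot(inherits(logged, "abundance_matrix"))
  if (logged$state != "log") stop("outlier flagging expects a log matrix")
  v <- logged$values
  if (ncol(v) < 2) stop("need at least 2 samples")
  n_obs <- colSums(!is.na(v))
  if (any(n_obs == 0)) {
    stop("sample(s) with no non-missing values: ",
         paste(colnames(v)[n_obs == 0], collapse = ", "))
  }
  pooled <- v[!is.na(v)]
  qs <- quantile(pooled, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  med <- apply(v, 2, median, na.rm = TRUE)
  dir <- classify_sample_medians(med, qs[1], qs[3])
  flagged <- data.frame(sample_id = colnames(v)[dir != "ok"],
                        log_median = unname(med[dir != "ok"]),
                        direction = dir[dir != "ok"],
                        stringsAsFactors = FALSE)
  rownames(flagged) <- NULL
  structure(
    list(sample_medians = med, dataset_median = qs[2],
         dataset_q1 = qs[1], dataset_q3 = qs[3], flagged = flagged),
    class = "outlier_report"
  )
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("outlier_report: dataset median %.2f, Q1 %.2f, Q3 %.2f\n",
              x$dataset_median, x$dataset_q1, x$dataset_q3))
  cat(sprintf("  %d of %d samples flagged\n", nrow(x$flagged),
              length(x$sample_medians)))
  if (nrow(x$flagged) > 0) print(x$flagged)
  invisible(x)
}

#' PCA scores of a log abundance matrix
#'
#' Samples are observations, metabolites variables. Metabolites with any
#' missing value are excluded listwise, and zero-variance metabolites are
#' excluded with a warning (they cannot be scaled to unit variance). The
#' matrix is centered and scaled to unit variance before decomposition
#' (stats::prcomp).
#'
#' @param logged `abundance_matrix` in `log` state.
#' @param n_components number of components to return.
#' @return list with `scores` (samples x components), `explained_variance`
#'   (fractions, non-increasing, summing to <= 1) and `excluded_metabolites`.
#' @export
pca_scores <- function(logged, n_components = 2L) {
  stopifnot(inherits(logged, "abundance_matrix"))
  if (logged$state != "log") stop("pca expects a log matrix")
  v <- logged$values
  if (ncol(v) < 2) stop("need at least 2 samples")
  has_na <- rowSums(is.na(v)) > 0
  zero_var <- !has_na & apply(v, 1, function(r) var(r) == 0)
  if (any(zero_var)) {
    warning("excluding zero-variance metabolite(s): ",
            paste(rownames(v)[zero_var], collapse = ", "))
  }
  keep <- !has_na & !zero_var
  if (sum(keep) < 2) stop("fewer than 2 usable metabolites for PCA")
  pr <- prcomp(t(v[keep, , drop = FALSE]), center = TRUE, scale. = TRUE)
  k <- min(n_components, ncol(pr$x))
  frac <- pr$sdev^2 / sum(pr$sdev^2)
  list(scores = pr$x[, seq_len(k), drop = FALSE],
       explained_variance = frac[seq_len(k)],
       excluded_metabolites = rownames(v)[!keep])
}
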