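#' Construct an abundance matrix
#'
#' Container for a metabolites x samples numeric matrix together with its
#' processing state. `raw_peak` holds arbitrary-unit GC-MS peak areas (may
#' include the internal-standard row), `normalized` holds abundances per mg
#' fresh weight after internal-standard and fresh-weight normalization, and
#' `log` holds log-transformed normalized abundances. Missing values (NA)
#' denote peaks not detected in a sample and are never imputed.
#'
#' @param values numeric matrix with metabolite row names and sample column
#'   names, both duplicate-free.
#' @param state one of `"raw_peak"`, `"normalized"`, `"log"`.
#' @param standard_id optional internal-standard metabolite id (e.g.
#'   `"Ribitol"`); must be a row of `values` when given.
#' @param log_base for `state = "log"`, the base used ("e", "10" or "2").
#' @return An object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(values, state = c("raw_peak", "normalized", "log"),
                             standard_id = NULL, log_base = NULL) {
  state <- match.arg(state)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must carry metabolite row names and sample column names")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate metabolite ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (state %in% c("raw_peak", "normalized") &&
      any(values < 0, na.rm = TRUE)) {
    stop("raw peak areas and normalized abundances must be non-negative")
  }
  if (!is.null(standard_id) && !standard_id %in% rownames(values)) {
    stop("internal standard '", standard_id, "' is not a row of the matrix")
  }
  structure(
    list(values = values, state = state, standard_id = standard_id,
         log_base = log_base),
    class = "abundance_matrix"
  )
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix [%s]: %d metabolites x %d samples\n",
              x$state, nrow(x$values), ncol(x$values)))
  if (!is.null(x$standard_id)) {
    cat("  internal standard:", x$standard_id, "\n")
  }
  n_na <- sum(is.na(x$values))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", n_na,
              100 * n_na / length(x$values)))
  invisible(x)
}

#' Metabolite ids of an abundance matrix
#' @param x an `abundance_matrix`.
#' @return character vector of metabolite ids.
#' @export
metabolite_ids <- function(x) rownames(x$values)

#' Sample ids of an abundance matrix
#' @param x an `abundance_matrix`.
#' @return character vector of sample ids.
#' @export
sample_ids <- function(x) colnames(x$values)

#' Metabolites not identified in a tissue
#'
#' A metabolite with NA values in all samples of a tissue was not identified
#' in that tissue. Recomputed after any sample filtering so that removals
#' never silently change a metabolite's detection status.
#'
#' @param abund an `abundance_matrix`.
#' @param meta sample metadata covering the matrix columns.
#' @return data.frame with columns `metabolite` and `tissue`, one row per
#'   (metabolite, tissue) pair in which the metabolite was never detected.
#' @export
not_identified_report <- function(abund, meta) {
  stopifnot(inherits(abund, "abundance_matrix"))
  meta <- meta[match(sample_ids(abund), meta$sample_id), , drop = FALSE]
  out <- list()
  for (tis in unique(meta$tissue)) {
    cols <- which(meta$tissue == tis)
    all_na <- rowSums(!is.na(abund$values[, cols, drop = FALSE])) == 0
    if (any(all_na)) {
      out[[tis]] <- data.frame(metabolite = rownames(abund$values)[all_na],
                               tissue = tis, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(metabolite = character(), tissue = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Drop samples from a matrix and its metadata
#'
#' Removes the given samples from both the abundance matrix and the metadata
#' table and recomputes the "not identified in tissue" report, so that QC
#' filtering never removes a metabolite's last observation silently.
#'
#' @param abund an `abundance_matrix`.
#' @param meta sample metadata.
#' @param drop character vector of sample ids to remove.
#' @return list with elements `abundance`, `meta` and `not_identified`.
#' @export
drop_samples <- function(abund, meta, drop) {
  stopifnot(inherits(abund, "abundance_matrix"))
  unknown <- setdiff(drop, sample_ids(abund))
  if (length(unknown) > 0) {
    stop("samples not in matrix: ", paste(unknown, collapse = ", "))
  }
  keep <- setdiff(sample_ids(abund), drop)
  out <- abundance_matrix(abund$values[, keep, drop = FALSE],
                          state = abund$state,
                          standard_id = abund$standard_id,
                          log_base = abund$log_base)
  meta <- meta[meta$sample_id %in% keep, , drop = FALSE]
  rownames(meta) <- NULL
  list(abundance = out, meta = meta,
       not_identified = not_identified_report(out, meta))
}
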