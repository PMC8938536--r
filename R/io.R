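sep_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read an abundance matrix and its sample metadata
#'
#' The matrix file is delimited text (TSV or CSV by extension) with one
#' header row: first column the metabolite id, remaining columns one per
#' sample. Empty fields and the token `NA` are parsed as missing, never as
#' zero. The metadata file must carry the columns `sample_id`, `genotype`,
#' `tissue`, `regime`, `day`, `replicate`, `fresh_weight_mg` (optionally
#' `batch`). Samples present in only one of the two files are reported and
#' dropped.
#'
#' @param matrix_path path to the abundance matrix file.
#' @param meta_path path to the sample metadata file.
#' @param state processing state of the stored values (default `raw_peak`).
#' @param standard_id optional internal-standard row id.
#' @return list with `abundance` (an [abundance_matrix()]), `meta`
#'   (data.frame) and `report` (dropped samples and the per-tissue
#'   "not identified" table).
#' @export
read_abundance <- function(matrix_path, meta_path,
                           state = "raw_peak", standard_id = NULL) {
  raw <- read.delim(matrix_path, sep = sep_for(matrix_path),
                    colClasses = "character", check.names = FALSE,
                    na.strings = c("", "NA"), stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("matrix file needs a metabolite column plus samples")
  met_ids <- raw[[1]]
  cells <- as.matrix(raw[, -1, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells),
                                 dimnames = list(met_ids, colnames(cells))))
  bad <- which(is.na(vals) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    b <- bad[1, ]
    stop(sprintf(
      "non-numeric abundance cell at metabolite '%s', sample '%s': '%s'",
      met_ids[b[1]], colnames(cells)[b[2]], cells[b[1], b[2]]))
  }

  meta <- read_sample_meta(meta_path)

  in_matrix <- colnames(vals)
  in_meta <- meta$sample_id
  common <- intersect(in_matrix, in_meta)
  if (length(common) == 0) stop("no samples shared between matrix and metadata")
  report <- list(
    samples_only_in_matrix = setdiff(in_matrix, in_meta),
    samples_only_in_meta = setdiff(in_meta, in_matrix)
  )
  vals <- vals[, common, drop = FALSE]
  meta <- meta[match(common, meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL

  abund <- abundance_matrix(vals, state = state, standard_id = standard_id)
  report$not_identified <- not_identified_report(abund, meta)
  list(abundance = abund, meta = meta, report = report)
}

#' Read a sample metadata table
#'
#' @param path TSV/CSV file with the mandatory metadata columns.
#' @return validated data.frame of sample metadata.
#' @export
read_sample_meta <- function(path) {
  meta <- read.delim(path, sep = sep_for(path), check.names = FALSE,
                     na.strings = c("", "NA"), stringsAsFactors = FALSE)
  missing_cols <- setdiff(META_REQUIRED_COLS, names(meta))
  if (length(missing_cols) > 0) {
    stop(paste(missing_cols, collapse = ", "), " required")
  }
  meta$sample_id <- as.character(meta$sample_id)
  meta$day <- as.integer(meta$day)
  meta$replicate <- as.integer(meta$replicate)
  meta$fresh_weight_mg <- as.numeric(meta$fresh_weight_mg)
  if (!"batch" %in% names(meta)) meta$batch <- NA_character_
  validate_sample_meta(meta)
  meta
}

#' Write an abundance matrix to delimited text
#'
#' First column `metabolite`, one column per sample; missing values written
#' as `NA`. Round-trips through [read_abundance()] bit-identically.
#'
#' @param abund an `abundance_matrix`.
#' @param path output file path (TSV, or CSV by extension).
#' @return `path`, invisibly.
#' @export
write_abundance <- function(abund, path) {
  stopifnot(inherits(abund, "abundance_matrix"))
  # %.17g guarantees an exact strtod round trip for doubles
  chr <- matrix(sprintf("%.17g", abund$values),
                nrow = nrow(abund$values), dimnames = dimnames(abund$values))
  chr[is.na(abund$values)] <- NA_character_
  df <- data.frame(metabolite = rownames(abund$values),
                   chr, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = sep_for(path), quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a sample metadata table
#'
#' @param meta data.frame of sample metadata.
#' @param path output file path (TSV, or CSV by extension).
#' @return `path`, invisibly.
#' @export
write_sample_meta <- function(meta, path) {
  validate_sample_meta(meta)
  write.table(meta, path, sep = sep_for(path), quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}
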