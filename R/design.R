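#' Enumerate the multifactorial sampling design
#'
#' Expands the factorial drought time-course design into one metadata row per
#' physical sample. Day 0 ("basal", before water is withheld) is shared by the
#' watered and drought series and is emitted exactly once per
#' genotype x tissue x replicate; each timed regime covers the requested days
#' >= 1. The full study design (3 genotypes x 2 tissues x 5 replicates x
#' (1 basal + 6 watered + 6 drought)) yields 390 samples.
#'
#' @param genotypes character vector of genotype levels.
#' @param tissues character vector of tissue levels.
#' @param regimes character vector drawn from `basal`, `watered`, `drought`.
#' @param days integer vector of sampling days; must contain 0 when `basal`
#'   is requested. Days >= 1 populate the timed regimes.
#' @param replicates integer vector of biological replicate identifiers.
#' @return A data.frame with columns `sample_id`, `genotype`, `tissue`,
#'   `regime`, `day`, `replicate`, `fresh_weight_mg` (NA; filled in by the
#'   generator or supplied with real data) and `batch` (NA).
#' @examples
#' d <- enumerate_design()
#' nrow(d) # 390
#' @export
enumerate_design <- function(genotypes = GENOTYPE_LEVELS,
                             tissues = TISSUE_LEVELS,
                             regimes = REGIME_LEVELS,
                             days = 0:6,
                             replicates = 1:5) {
  for (nm in c("genotypes", "tissues", "regimes", "days", "replicates")) {
    v <- get(nm)
    if (length(v) == 0) stop("empty factor set: ", nm)
    if (anyDuplicated(v)) stop("duplicate ", sub("s$", "", nm), " ids in ", nm)
  }
  if (!all(regimes %in% REGIME_LEVELS)) {
    stop("unknown regime(s): ", paste(setdiff(regimes, REGIME_LEVELS), collapse = ", "))
  }
  days <- as.integer(days)
  replicates <- as.integer(replicates)
  if (any(days < 0)) stop("days must be non-negative")
  if ("basal" %in% regimes && !0 %in% days) {
    stop("days must include 0 when the basal regime is requested")
  }

  blocks <- list()
  if ("basal" %in% regimes) {
    blocks$basal <- expand.grid(
      genotype = genotypes, tissue = tissues, regime = "basal",
      day = 0L, replicate = replicates,
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
  }
  timed_days <- days[days >= 1L]
  for (rg in intersect(c("watered", "drought"), regimes)) {
    if (length(timed_days) > 0) {
      blocks[[rg]] <- expand.grid(
        genotype = genotypes, tissue = tissues, regime = rg,
        day = timed_days, replicate = replicates,
        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
      )
    }
  }
  if (length(blocks) == 0) stop("requested design is empty")
  meta <- do.call(rbind, blocks)
  ord <- order(meta$genotype, meta$tissue,
               match(meta$regime, REGIME_LEVELS), meta$day, meta$replicate)
  meta <- meta[ord, , drop = FALSE]
  meta$sample_id <- sprintf("%s_%s_%s_d%d_r%d", meta$genotype, meta$tissue,
                            meta$regime, meta$day, meta$replicate)
  meta$fresh_weight_mg <- NA_real_
  meta$batch <- NA_character_
  rownames(meta) <- NULL
  meta <- meta[, c("sample_id", "genotype", "tissue", "regime", "day",
                   "replicate", "fresh_weight_mg", "batch")]
  validate_sample_meta(meta, require_fresh_weight = FALSE)
  meta
}

#' Validate a sample metadata table
#'
#' Checks the design invariants: mandatory columns present, factor levels
#' legal, `regime == "basal"` if and only if `day == 0`, positive fresh
#' weights (when present), and uniqueness of the
#' (genotype, tissue, regime, day, replicate) coordinates.
#'
#' @param meta data.frame of sample metadata.
#' @param require_fresh_weight logical; when TRUE every sample must carry a
#'   positive fresh weight (needed for normalization).
#' @return `meta`, invisibly, after validation.
#' @export
validate_sample_meta <- function(meta, require_fresh_weight = FALSE) {
  missing_cols <- setdiff(META_REQUIRED_COLS, names(meta))
  if (length(missing_cols) > 0) {
    stop(paste(missing_cols, collapse = ", "), " required")
  }
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id values")
  if (!all(meta$tissue %in% TISSUE_LEVELS)) {
    stop("unknown tissue level(s): ",
         paste(unique(setdiff(meta$tissue, TISSUE_LEVELS)), collapse = ", "))
  }
  if (!all(meta$regime %in% REGIME_LEVELS)) {
    stop("unknown regime level(s): ",
         paste(unique(setdiff(meta$regime, REGIME_LEVELS)), collapse = ", "))
  }
  basal <- meta$regime == "basal"
  if (any(basal != (meta$day == 0))) {
    stop("regime 'basal' must coincide exactly with day 0")
  }
  fw <- meta$fresh_weight_mg
  if (require_fresh_weight && anyNA(fw)) {
    stop("fresh_weight_mg required for all samples; missing for: ",
         paste(utils::head(meta$sample_id[is.na(fw)], 5), collapse = ", "))
  }
  if (any(!is.na(fw) & fw <= 0)) stop("fresh_weight_mg must be positive")
  key <- interaction(meta$genotype, meta$tissue, meta$regime, meta$day,
                     meta$replicate, drop = TRUE)
  if (anyDuplicated(key)) {
    stop("duplicate (genotype, tissue, regime, day, replicate) coordinates")
  }
  invisible(meta)
}
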