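# Vectorized pooled-variance Student t-test over the rows of two matrices.
# Convention: t = (mean_a - mean_b) / se. Zero pooled variance with equal
# means gives t = 0, p = 1; with unequal means p = 0.
pooled_t_rows <- function(xa, xb) {
  na <- rowSums(!is.na(xa))
  nb <- rowSums(!is.na(xb))
  ma <- rowMeans(xa, na.rm = TRUE)
  mb <- rowMeans(xb, na.rm = TRUE)
  va <- (rowSums(xa^2, na.rm = TRUE) - na * ma^2) / pmax(na - 1, 1)
  vb <- (rowSums(xb^2, na.rm = TRUE) - nb * mb^2) / pmax(nb - 1, 1)
  va <- pmax(va, 0)  # guard tiny negative from cancellation
  vb <- pmax(vb, 0)
  df <- na + nb - 2
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tt <- (ma - mb) / se
  p <- 2 * pt(-abs(tt), df)
  zero_se <- !is.na(se) & se == 0
  tt[zero_se & ma == mb] <- 0
  p[zero_se & ma == mb] <- 1
  p[zero_se & ma != mb] <- 0
  data.frame(n_a = na, n_b = nb, mean_a = ma, mean_b = mb,
             t = tt, df = df, p = p)
}

comparison_table <- function(xa, xb, log_scale, alpha) {
  tt <- pooled_t_rows(xa, xb)
  med_a <- apply(xa, 1, median, na.rm = TRUE)
  med_b <- apply(xb, 1, median, na.rm = TRUE)
  # fold-change of b relative to a, on the log scale; the median commutes
  # with log, so the difference of log-medians is log(median_b / median_a)
  log_fc <- if (log_scale) med_b - med_a else log(med_b / med_a)
  tested <- tt$n_a >= 2 & tt$n_b >= 2
  res <- data.frame(metabolite = rownames(xa), tt,
                    median_a = med_a, median_b = med_b, log_fc = log_fc,
                    stringsAsFactors = FALSE)
  res$t[!tested] <- NA_real_
  res$p[!tested] <- NA_real_
  res$q <- NA_real_
  res$q[tested] <- p.adjust(res$p[tested], method = "BH")
  res$significant <- !is.na(res$p) & res$p < alpha
  rownames(res) <- NULL
  structure(res, class = c("comparison_result", "data.frame"),
            alpha = alpha,
            not_tested = res$metabolite[!tested])
}

#' Pairwise group comparison with Student's t-test
#'
#' Two-sided pooled-variance Student's t-test per metabolite between two
#' levels of a design factor, within an optional condition filter (e.g. one
#' tissue at one day). Fold-changes are log fold-changes of group b relative
#' to the group-a median, matching the convention of reporting accumulation
#' relative to the WT median. Metabolites with fewer than 2 non-missing
#' values in either group are reported as not tested. Benjamini-Hochberg
#' adjusted q-values are reported alongside the raw p-values; the default
#' significance call uses raw p < 0.025.
#'
#' @param abund `abundance_matrix` in `normalized` or `log` state.
#' @param meta sample metadata.
#' @param factor metadata column to compare on (e.g. `"genotype"`).
#' @param level_a,level_b reference and comparison levels.
#' @param at optional named list restricting samples, e.g.
#'   `list(tissue = "root", day = 0)`.
#' @param alpha raw-p significance threshold (default 0.025).
#' @return data.frame of class `comparison_result` with per-metabolite
#'   `t`, `df`, `p`, `q`, medians, `log_fc` and `significant`.
#' @export
compare_groups <- function(abund, meta, factor, level_a, level_b,
                           at = NULL, alpha = 0.025) {
  stopifnot(inherits(abund, "abundance_matrix"))
  if (abund$state == "raw_peak") {
    stop("compare_groups expects a normalized or log matrix")
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0,1)")
  if (!factor %in% names(meta)) stop("unknown factor: ", factor)
  meta <- meta[match(sample_ids(abund), meta$sample_id), , drop = FALSE]
  keep <- rep(TRUE, nrow(meta))
  for (nm in names(at)) {
    if (!nm %in% names(meta)) stop("unknown filter column: ", nm)
    keep <- keep & meta[[nm]] %in% at[[nm]]
  }
  ids_a <- meta$sample_id[keep & meta[[factor]] == level_a]
  ids_b <- meta$sample_id[keep & meta[[factor]] == level_b]
  if (length(ids_a) < 2 || length(ids_b) < 2) {
    stop("each group needs at least 2 samples (got ", length(ids_a), " and ",
         length(ids_b), ")")
  }
  xa <- abund$values[, ids_a, drop = FALSE]
  xb <- abund$values[, ids_b, drop = FALSE]
  res <- comparison_table(xa, xb, log_scale = abund$state == "log",
                          alpha = alpha)
  attr(res, "levels") <- c(a = level_a, b = level_b)
  attr(res, "group_sizes") <- c(a = length(ids_a), b = length(ids_b))
  res
}

#' Paired shoot/root ratio matrix
#'
#' Builds the derived shoot-to-root variable from samples paired by
#' (genotype, regime, day, replicate). Pairs lacking either tissue after QC
#' are dropped and listed, mirroring the rule that discarding one tissue's
#' replicate discards its paired counterpart. Ratios are reported as
#' log-ratios; a zero or missing value in either tissue yields a missing
#' ratio (with a warning for zero denominators).
#'
#' @param abund `abundance_matrix` in `normalized` or `log` state containing
#'   both tissues.
#' @param meta sample metadata.
#' @return object of class `ratio_matrix`: `log_ratios` (metabolites x
#'   pairs), `pairs` (pairing table) and `dropped_pairs`.
#' @export
shoot_root_ratios <- function(abund, meta) {
  stopifnot(inherits(abund, "abundance_matrix"))
  if (abund$state == "raw_peak") {
    stop("shoot_root_ratios expects a normalized or log matrix")
  }
  meta <- meta[match(sample_ids(abund), meta$sample_id), , drop = FALSE]
  key <- sprintf("%s_%s_d%d_r%d", meta$genotype, meta$regime, meta$day,
                 meta$replicate)
  shoot <- meta$tissue == "shoot"
  root <- meta$tissue == "root"
  shoot_map <- setNames(meta$sample_id[shoot], key[shoot])
  root_map <- setNames(meta$sample_id[root], key[root])
  common <- intersect(names(shoot_map), names(root_map))
  only <- c(setdiff(names(shoot_map), names(root_map)),
            setdiff(names(root_map), names(shoot_map)))
  dropped <- data.frame(
    pair_id = only,
    missing_tissue = c(rep("root", sum(!names(shoot_map) %in% names(root_map))),
                       rep("shoot", sum(!names(root_map) %in% names(shoot_map)))),
    stringsAsFactors = FALSE
  )
  if (length(common) == 0) stop("no shoot/root pairs present")
  vs <- abund$values[, shoot_map[common], drop = FALSE]
  vr <- abund$values[, root_map[common], drop = FALSE]
  if (abund$state == "log") {
    lr <- vs - vr
  } else {
    zero <- (!is.na(vr) & vr == 0) | (!is.na(vs) & vs == 0)
    if (any(zero)) {
      warning(sum(zero), " ratio cell(s) undefined (zero abundance); set to NA")
    }
    vs[zero] <- NA
    vr[zero] <- NA
    lr <- log(vs / vr)
  }
  colnames(lr) <- common
  pair_meta <- meta[match(shoot_map[common], meta$sample_id),
                    c("genotype", "regime", "day", "replicate")]
  pairs <- data.frame(pair_id = common, pair_meta,
                      shoot_sample = unname(shoot_map[common]),
                      root_sample = unname(root_map[common]),
                      stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  structure(list(log_ratios = lr, pairs = pairs, dropped_pairs = dropped),
            class = "ratio_matrix")
}

#' Compare shoot/root log-ratios between groups
#'
#' Applies the same pooled-variance Student's t-test engine to the paired
#' log-ratio matrix, comparing two levels of a pairing factor (genotype,
#' regime or day).
#'
#' @param ratios a [shoot_root_ratios()] result.
#' @param factor one of `"genotype"`, `"regime"`, `"day"`.
#' @param level_a,level_b levels to compare.
#' @param at optional named list filtering the pairs.
#' @param alpha raw-p significance threshold (default 0.025).
#' @return data.frame of class `comparison_result`.
#' @export
compare_ratio_groups <- function(ratios, factor, level_a, level_b,
                                 at = NULL, alpha = 0.025) {
  stopifnot(inherits(ratios, "ratio_matrix"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0,1)")
  pairs <- ratios$pairs
  if (!factor %in% names(pairs)) stop("unknown pairing factor: ", factor)
  keep <- rep(TRUE, nrow(pairs))
  for (nm in names(at)) keep <- keep & pairs[[nm]] %in% at[[nm]]
  ids_a <- pairs$pair_id[keep & pairs[[factor]] == level_a]
  ids_b <- pairs$pair_id[keep & pairs[[factor]] == level_b]
  if (length(ids_a) < 2 || length(ids_b) < 2) {
    stop("each group needs at least 2 pairs (got ", length(ids_a), " and ",
         length(ids_b), ")")
  }
  res <- comparison_table(ratios$log_ratios[, ids_a, drop = FALSE],
                          ratios$log_ratios[, ids_b, drop = FALSE],
                          log_scale = TRUE, alpha = alpha)
  attr(res, "levels") <- c(a = level_a, b = level_b)
  res
}
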