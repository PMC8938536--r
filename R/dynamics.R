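# Residual sums of squares of a multi-response least-squares fit.
rss_qr <- function(qr_x, Y) colSums(qr.resid(qr_x, Y)^2)

f_pvalue <- function(rss_small, rss_big, df_num, df_den, tol = 1e-12) {
  scale <- pmax(rss_small, rss_big, 1)
  num <- pmax(rss_small - rss_big, 0) / df_num
  den <- rss_big / df_den
  p <- pf(num / den, df_num, df_den, lower.tail = FALSE)
  # degenerate fits: an (almost) exact fit of the smaller model means no
  # evidence for the extra terms; an exact big fit with real improvement is
  # overwhelming evidence
  exact_small <- (rss_small - rss_big) <= tol * scale
  exact_big <- den <= tol * scale / df_den
  p[exact_big & exact_small] <- 1
  p[exact_big & !exact_small] <- 0
  p
}

#' Fit polynomial time-course models per metabolite
#'
#' For one tissue and one watering series (drought or watered, each with the
#' shared basal day 0), fits per metabolite the full model
#' `value ~ genotype * (day + day^2 + ... + day^degree)` with day as a
#' continuous covariate, by least squares. Two F-tests are reported:
#' *global* (all time and genotype terms vs the intercept-only model: any
#' time dependence) and *differential* (all genotype and genotype x time
#' terms vs the reference-genotype-only polynomial: genotype-specific
#' dynamics). P-values are Benjamini-Hochberg adjusted across metabolites.
#'
#' @param abund `abundance_matrix` in `log` (recommended) or `normalized`
#'   state.
#' @param meta sample metadata.
#' @param tissue tissue to analyze (one at a time).
#' @param degree polynomial degree (default 2, quadratic).
#' @param reference_genotype genotype whose polynomial is the reference.
#' @param series `"drought"` or `"watered"`.
#' @return data.frame of class `dynamics_fit` with per-metabolite
#'   `p_global`, `q_global`, `p_diff`, `q_diff`, `r2`, `n_obs`; attributes
#'   `coefficients` (full-model coefficient matrix), `design` and
#'   `skipped_metabolites`.
#' @export
fit_time_course <- function(abund, meta, tissue, degree = 2L,
                            reference_genotype = "WT",
                            series = c("drought", "watered")) {
  stopifnot(inherits(abund, "abundance_matrix"))
  series <- match.arg(series)
  if (abund$state == "raw_peak") {
    stop("fit_time_course expects a normalized or log matrix")
  }
  degree <- as.integer(degree)
  if (degree < 1) stop("degree must be >= 1")
  meta <- meta[match(sample_ids(abund), meta$sample_id), , drop = FALSE]
  sel <- meta$tissue == tissue & meta$regime %in% c("basal", series)
  if (!any(sel)) stop("no samples for tissue '", tissue, "', series ", series)
  meta <- meta[sel, , drop = FALSE]
  Y <- t(abund$values[, meta$sample_id, drop = FALSE])
  n_days <- length(unique(meta$day))
  if (n_days < degree + 2) {
    stop("need at least degree + 2 distinct days (have ", n_days, ")")
  }
  genos <- unique(meta$genotype)
  if (!reference_genotype %in% genos) {
    stop("reference genotype '", reference_genotype, "' absent from series")
  }
  geno <- factor(meta$genotype,
                 levels = c(reference_genotype,
                            setdiff(genos, reference_genotype)))
  day <- as.numeric(meta$day)
  dat <- data.frame(day = day, genotype = geno)
  x_full <- model.matrix(~ genotype * poly(day, degree, raw = TRUE), dat)
  x_ref <- model.matrix(~ poly(day, degree, raw = TRUE), dat)
  n <- nrow(x_full)
  p_full <- qr(x_full)$rank
  p_ref <- qr(x_ref)$rank
  if (n <= p_full) stop("not enough samples for the full model")

  met_ids <- colnames(Y)
  n_obs <- colSums(!is.na(Y))
  res <- data.frame(metabolite = met_ids, p_global = NA_real_,
                    p_diff = NA_real_, r2 = NA_real_, n_obs = n_obs,
                    stringsAsFactors = FALSE)
  coefs <- matrix(NA_real_, nrow = length(met_ids), ncol = ncol(x_full),
                  dimnames = list(met_ids, colnames(x_full)))
  skipped <- character()

  qr_full <- qr(x_full)
  qr_ref <- qr(x_ref)
  complete <- n_obs == n
  if (any(complete)) {
    Yc <- Y[, complete, drop = FALSE]
    rss0 <- colSums(scale(Yc, scale = FALSE)^2)
    rss_ref <- rss_qr(qr_ref, Yc)
    rss_full <- rss_qr(qr_full, Yc)
    res$p_global[complete] <-
      f_pvalue(rss0, rss_full, p_full - 1, n - p_full)
    res$p_diff[complete] <-
      f_pvalue(rss_ref, rss_full, p_full - p_ref, n - p_full)
    res$r2[complete] <- ifelse(rss0 > 0, 1 - rss_full / rss0, 0)
    coefs[complete, ] <- t(qr.coef(qr_full, Yc))
  }
  for (j in which(!complete)) {
    ok <- !is.na(Y[, j])
    if (sum(ok) <= p_full || length(unique(day[ok])) < degree + 2 ||
        !all(levels(geno) %in% unique(as.character(geno[ok])))) {
      skipped <- c(skipped, met_ids[j])
      next
    }
    y <- Y[ok, j]
    xf <- x_full[ok, , drop = FALSE]
    xr <- x_ref[ok, , drop = FALSE]
    qf <- qr(xf)
    rss0 <- sum((y - mean(y))^2)
    rss_r <- sum(qr.resid(qr(xr), y)^2)
    rss_f <- sum(qr.resid(qf, y)^2)
    nn <- sum(ok)
    res$p_global[j] <- f_pvalue(rss0, rss_f, p_full - 1, nn - p_full)
    res$p_diff[j] <- f_pvalue(rss_r, rss_f, p_full - p_ref, nn - p_full)
    res$r2[j] <- if (rss0 > 0) 1 - rss_f / rss0 else 0
    coefs[j, ] <- qr.coef(qf, y)
  }
  fitted_rows <- !res$metabolite %in% skipped & !is.na(res$p_diff)
  res$q_global <- NA_real_
  res$q_diff <- NA_real_
  res$q_global[fitted_rows] <- p.adjust(res$p_global[fitted_rows], "BH")
  res$q_diff[fitted_rows] <- p.adjust(res$p_diff[fitted_rows], "BH")
  res <- res[, c("metabolite", "p_global", "q_global", "p_diff", "q_diff",
                 "r2", "n_obs")]
  rownames(res) <- NULL
  structure(res, class = c("dynamics_fit", "data.frame"),
            coefficients = coefs,
            design = list(tissue = tissue, series = series, degree = degree,
                          reference_genotype = reference_genotype,
                          genotypes = levels(geno), n_samples = n),
            skipped_metabolites = skipped)
}

#' Select metabolites with differential dynamics
#'
#' @param fits a [fit_time_course()] result.
#' @param q_threshold BH-adjusted differential q-value cut-off (default
#'   0.05).
#' @param r2_min minimum full-model R-squared, a fit-quality gate (default
#'   0.6).
#' @return character vector of selected metabolite ids.
#' @export
select_differential <- function(fits, q_threshold = 0.05, r2_min = 0.6) {
  stopifnot(inherits(fits, "dynamics_fit"))
  if (q_threshold < 0) stop("q_threshold must be non-negative")
  sel <- !is.na(fits$q_diff) & fits$q_diff < q_threshold &
    !is.na(fits$r2) & fits$r2 >= r2_min
  fits$metabolite[sel]
}

#' Cluster selected metabolites by their median time profile
#'
#' Builds the per-metabolite median profile across replicates per
#' (genotype, day), standardizes each profile to zero mean and unit
#' variance, and cuts a complete-linkage hierarchical clustering of the
#' Euclidean distances into `k` clusters. Identical profiles always land in
#' the same cluster.
#'
#' @param abund `abundance_matrix` in `normalized` or `log` state.
#' @param meta sample metadata.
#' @param selected metabolite ids to cluster (>= k).
#' @param k number of clusters.
#' @param tissue tissue to profile.
#' @param series `"drought"` or `"watered"`.
#' @return named integer vector of cluster labels over `selected`.
#' @export
cluster_profiles <- function(abund, meta, selected, k, tissue,
                             series = c("drought", "watered")) {
  stopifnot(inherits(abund, "abundance_matrix"))
  series <- match.arg(series)
  selected <- as.character(selected)
  if (length(selected) == 0) stop("no metabolites selected")
  if (k < 1 || k > length(selected)) {
    stop("k must lie between 1 and the number of selected metabolites")
  }
  if (!all(selected %in% rownames(abund$values))) {
    stop("unknown metabolite id(s) in selection")
  }
  meta <- meta[match(sample_ids(abund), meta$sample_id), , drop = FALSE]
  sel <- meta$tissue == tissue & meta$regime %in% c("basal", series)
  meta <- meta[sel, , drop = FALSE]
  v <- abund$values[selected, meta$sample_id, drop = FALSE]
  grp <- interaction(meta$genotype, meta$day, drop = TRUE, lex.order = TRUE)
  prof <- t(apply(v, 1, function(r) {
    tapply(r, grp, median, na.rm = TRUE)
  }))
  prof <- t(apply(prof, 1, function(r) {
    s <- sd(r, na.rm = TRUE)
    if (is.na(s) || s == 0) rep(0, length(r)) else (r - mean(r, na.rm = TRUE)) / s
  }))
  prof[is.na(prof)] <- 0
  hc <- hclust(dist(prof), method = "complete")
  cutree(hc, k = k)
}
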