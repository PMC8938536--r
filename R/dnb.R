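#' Composite index of a dynamical-network-biomarker cluster
#'
#' The per-cluster early-warning score `CI = SDin * PCCin / PCCout`: average
#' within-cluster standard deviation times average absolute within-cluster
#' Pearson correlation, divided by the average absolute correlation between
#' members and non-members. A critical transition is signalled by a sharp
#' CI rise.
#'
#' @param sdin mean member standard deviation (standardized scale), >= 0.
#' @param pccin mean absolute within-cluster Pearson correlation, in
#'   \[0, 1\].
#' @param pccout mean absolute member/non-member correlation, in \[0, 1\];
#'   must be positive.
#' @return the composite index, a non-negative number.
#' @examples
#' compute_ci(0.93, 0.45, 0.38) # 1.10 at 2 d.p.
#' @export
compute_ci <- function(sdin, pccin, pccout) {
  if (any(is.na(c(sdin, pccin, pccout)))) stop("CI inputs must be non-missing")
  if (any(sdin < 0)) stop("sdin must be non-negative")
  if (any(pccin < 0 | pccin > 1)) stop("pccin must lie in [0,1]")
  if (any(pccout > 1)) stop("pccout must lie in [0,1]")
  if (any(pccout <= 0)) stop("undefined composite index: pccout must be positive")
  sdin * pccin / pccout
}

#' Standardize a log matrix against a reference condition
#'
#' Z-scores every metabolite against the mean and standard deviation of the
#' reference samples (by default the pre-treatment day 0, which serves as
#' the control for the case samples of drought days 1-6). Metabolites whose
#' reference standard deviation is zero (or undefined) are excluded with a
#' record.
#'
#' @param logged `abundance_matrix` in `log` state.
#' @param meta sample metadata.
#' @param reference named list of metadata filters selecting the reference
#'   samples (default `list(day = 0)`); >= 2 reference samples required.
#' @return list with `z` (standardized metabolites x samples matrix over all
#'   input samples), `excluded_metabolites`, and `reference_samples`.
#' @export
standardize_to_reference <- function(logged, meta, reference = list(day = 0)) {
  stopifnot(inherits(logged, "abundance_matrix"))
  if (logged$state != "log") stop("standardization expects a log matrix")
  meta <- meta[match(sample_ids(logged), meta$sample_id), , drop = FALSE]
  keep <- rep(TRUE, nrow(meta))
  for (nm in names(reference)) {
    if (!nm %in% names(meta)) stop("unknown reference filter: ", nm)
    keep <- keep & meta[[nm]] %in% reference[[nm]]
  }
  ref_ids <- meta$sample_id[keep]
  if (length(ref_ids) < 2) stop("reference group needs at least 2 samples")
  ref <- logged$values[, ref_ids, drop = FALSE]
  m <- rowMeans(ref, na.rm = TRUE)
  s <- apply(ref, 1, sd, na.rm = TRUE)
  usable <- !is.na(s) & s > 0 & rowSums(!is.na(ref)) >= 2
  z <- (logged$values[usable, , drop = FALSE] - m[usable]) / s[usable]
  list(z = z,
       excluded_metabolites = rownames(logged$values)[!usable],
       reference_samples = ref_ids)
}

# Per-day statistics of a fixed metabolite partition: SDin, PCCin, PCCout
# and CI computed from the replicates at one day (standardized scale).
cluster_stats_at_day <- function(z_day, labels, min_cluster_size) {
  usable <- apply(z_day, 1, function(r) !anyNA(r) && sd(r) > 0)
  z_day <- z_day[usable, , drop = FALSE]
  labels <- labels[rownames(z_day)]
  if (nrow(z_day) < 2) return(NULL)
  cmat <- abs(cor(t(z_day)))
  sds <- apply(z_day, 1, sd)
  out <- list()
  for (cl in sort(unique(labels))) {
    members <- names(labels)[labels == cl]
    if (length(members) < min_cluster_size) next
    others <- setdiff(rownames(z_day), members)
    cin <- cmat[members, members, drop = FALSE]
    pccin <- mean(cin[upper.tri(cin)])
    pccout <- if (length(others) > 0) {
      mean(cmat[members, others, drop = FALSE])
    } else {
      NA_real_
    }
    sdin <- mean(sds[members])
    ci <- if (!is.na(pccout) && pccout > 0) {
      compute_ci(sdin, min(pccin, 1), min(pccout, 1))
    } else {
      NA_real_
    }
    out[[length(out) + 1]] <- list(cluster = cl, members = members,
                                   SDin = sdin, PCCin = pccin,
                                   PCCout = pccout, CI = ci)
  }
  out
}

# Metabolite modules: one complete-linkage clustering on the distance
# 1 - |Pearson correlation| across all pooled case samples. Pooling the
# whole case series gives the correlation estimate enough samples to hold a
# module together; the per-day statistics then probe when that module's
# variance and intra-correlation spike.
dnb_modules <- function(z_case, k_clusters) {
  usable <- apply(z_case, 1, function(r) !anyNA(r) && sd(r) > 0)
  z_case <- z_case[usable, , drop = FALSE]
  if (nrow(z_case) < 2) stop("too few usable metabolites for clustering")
  cmat <- abs(cor(t(z_case)))
  k <- min(k_clusters, nrow(z_case))
  hc <- hclust(as.dist(1 - cmat), method = "complete")
  cutree(hc, k = k)
}

#' Detect dynamical network biomarkers along the drought time course
#'
#' For one genotype and tissue, standardizes log abundances against the
#' day-0 controls, identifies metabolite modules by complete-linkage
#' hierarchical clustering on the distance `1 - |Pearson correlation|`
#' computed across all pooled drought case samples (days 1-6), then for each
#' day computes `SDin`, `PCCin`, `PCCout` and the composite index of every
#' module of sufficient size from the replicates at that day. The DNB is
#' the module whose CI spikes most sharply relative to its own trajectory
#' (max/median), and the critical point is that module's CI-maximum day
#' (ties broken toward the earlier day, the early-warning reading).
#' Clustering once on the pooled case series keeps module membership stable
#' across days, which a handful of replicates per day cannot; the spike
#' ratio is invariant to the scale noise of the day-0 standardization.
#'
#' @param logged `abundance_matrix` in `log` state.
#' @param meta sample metadata.
#' @param genotype,tissue condition analyzed.
#' @param k_clusters number of clusters to cut per day (default 10).
#' @param min_cluster_size smallest admissible cluster (default 2; reported
#'   DNBs can have as few as 2 members).
#' @param days drought days analyzed (default 1:6).
#' @return object of class `dnb_result`: `stats` (per day x module: module
#'   id, members, SDin, PCCin, PCCout, CI), `critical_point`, `dnb_members`
#'   (the maximizing module), `modules` (the full partition), and
#'   `excluded_metabolites` from the standardization.
#' @export
detect_dnb <- function(logged, meta, genotype, tissue, k_clusters = 10L,
                       min_cluster_size = 2L, days = 1:6) {
  stopifnot(inherits(logged, "abundance_matrix"))
  meta <- meta[match(sample_ids(logged), meta$sample_id), , drop = FALSE]
  sel <- meta$genotype == genotype & meta$tissue == tissue &
    (meta$regime == "basal" | (meta$regime == "drought" & meta$day %in% days))
  if (!any(sel)) stop("no samples for ", genotype, " ", tissue)
  meta <- meta[sel, , drop = FALSE]
  sub <- abundance_matrix(logged$values[, meta$sample_id, drop = FALSE],
                          state = "log", log_base = logged$log_base)
  n_per_day <- table(factor(meta$day[meta$regime == "drought"], levels = days))
  if (any(n_per_day < 3)) {
    stop("fewer than 3 replicates at day(s) ",
         paste(days[n_per_day < 3], collapse = ", "),
         "; correlation estimates unstable")
  }
  std <- standardize_to_reference(sub, meta, reference = list(day = 0))
  if (nrow(std$z) < min_cluster_size) stop("too few usable metabolites")

  case_cols <- meta$sample_id[meta$regime == "drought" & meta$day %in% days]
  modules <- dnb_modules(std$z[, case_cols, drop = FALSE], k_clusters)
  if (max(table(modules)) < min_cluster_size) {
    stop("no module reached min_cluster_size")
  }

  rows <- list()
  for (d in days) {
    cols <- meta$sample_id[meta$regime == "drought" & meta$day == d]
    stats <- cluster_stats_at_day(std$z[names(modules), cols, drop = FALSE],
                                  modules, min_cluster_size)
    if (is.null(stats) || length(stats) == 0) next
    for (st in stats) {
      rows[[length(rows) + 1]] <- data.frame(
        day = d, module = st$cluster, size = length(st$members),
        members = paste(sort(st$members), collapse = ";"),
        SDin = st$SDin, PCCin = st$PCCin, PCCout = st$PCCout, CI = st$CI,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    stop("no module reached min_cluster_size at any day")
  }
  stats_df <- do.call(rbind, rows)
  rownames(stats_df) <- NULL
  if (all(is.na(stats_df$CI))) stop("composite index undefined for every module")

  # The DNB is the module whose CI rises most sharply along its own
  # trajectory (max/median spike ratio): the method's criteria are drastic
  # *increases*, and the ratio is exactly invariant to the per-metabolite
  # scale noise of the day-0 reference standardization. The critical point
  # is that module's CI-maximum day, ties broken toward the earlier day.
  spike <- function(tr) {
    tr <- tr[!is.na(tr)]
    if (length(tr) == 0) return(-Inf)
    med <- median(tr)
    if (med <= 0) return(max(tr))
    max(tr) / med
  }
  scores <- tapply(stats_df$CI, stats_df$module, spike)
  winner <- as.integer(names(scores)[which.max(scores)])
  wrows <- stats_df[stats_df$module == winner & !is.na(stats_df$CI), ]
  best <- wrows[wrows$CI == max(wrows$CI), ]
  best <- best[which.min(best$day), ]
  structure(
    list(stats = stats_df,
         critical_point = best$day,
         dnb_members = strsplit(best$members, ";")[[1]],
         dnb_module = winner,
         spike_ratio = unname(scores[as.character(winner)]),
         modules = modules,
         excluded_metabolites = std$excluded_metabolites),
    class = "dnb_result"
  )
}

#' @export
print.dnb_result <- function(x, ...) {
  cat(sprintf("dnb_result: critical point day %d, CI %.3f\n",
              x$critical_point,
              max(x$stats$CI, na.rm = TRUE)))
  cat("  DNB members:", paste(x$dnb_members, collapse = ", "), "\n")
  invisible(x)
}
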