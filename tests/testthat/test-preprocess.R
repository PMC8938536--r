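make_raw <- function(n_met = 20, n_samp = 12, seed = 1, na_frac = 0.1) {
  meta <- flat_meta(replicates = seq_len(ceiling(n_samp / 13)))
  meta <- meta[seq_len(n_samp), ]
  v <- random_matrix(n_met, n_samp, seed = seed, na_frac = na_frac)
  v <- rbind(Ribitol = rlnorm(n_samp), v)
  colnames(v) <- meta$sample_id
  list(ab = abundance_matrix(v, "raw_peak", standard_id = "Ribitol"),
       meta = meta)
}

test_that("normalization matches element-wise brute-force recomputation", {
  x <- make_raw(20, 12, seed = 8)
  norm <- normalize_abundance(x$ab, x$meta)
  expect_equal(norm$state, "normalized")
  expect_false("Ribitol" %in% rownames(norm$values))
  # oracle: direct loop over cells
  fw <- setNames(x$meta$fresh_weight_mg, x$meta$sample_id)
  for (m in rownames(norm$values)) {
    for (s in colnames(norm$values)) {
      expect_identical(norm$values[m, s],
                       x$ab$values[m, s] / x$ab$values["Ribitol", s] / fw[[s]])
    }
  }
  # missing stays missing, never zero
  expect_identical(is.na(norm$values), is.na(x$ab$values[-1, ]))
})

test_that("normalization cancels per-sample detector gain", {
  x <- make_raw(10, 6, seed = 9, na_frac = 0)
  norm0 <- normalize_abundance(x$ab, x$meta)
  # power-of-two gain: cancellation is exact in IEEE arithmetic
  gained <- x$ab$values
  gained[, 3] <- gained[, 3] * 8
  norm8 <- normalize_abundance(
    abundance_matrix(gained, "raw_peak", standard_id = "Ribitol"), x$meta)
  expect_identical(norm8$values, norm0$values)
  # arbitrary gain: invariant to floating-point rounding
  gained <- x$ab$values
  gained[, 5] <- gained[, 5] * 7
  norm7 <- normalize_abundance(
    abundance_matrix(gained, "raw_peak", standard_id = "Ribitol"), x$meta)
  expect_equal(norm7$values, norm0$values, tolerance = 1e-14)
})

test_that("normalization contract failures name the offending sample", {
  x <- make_raw(5, 4, seed = 10, na_frac = 0)
  bad <- x$ab$values
  bad["Ribitol", 2] <- 0
  expect_error(
    normalize_abundance(abundance_matrix(bad, "raw_peak",
                                         standard_id = "Ribitol"), x$meta),
    x$meta$sample_id[2])
  meta2 <- x$meta
  meta2$fresh_weight_mg[3] <- NA
  expect_error(normalize_abundance(x$ab, meta2), "fresh_weight_mg")
})

test_that("log transform obeys closed forms and preserves missingness", {
  x <- make_raw(6, 5, seed = 11)
  norm <- normalize_abundance(x$ab, x$meta)
  l10 <- log_transform(norm, "10")
  le <- log_transform(norm, "e")
  expect_equal(le$values / log(10), l10$values, tolerance = 1e-12)
  expect_identical(is.na(l10$values), is.na(norm$values))

  ones <- abundance_matrix(
    matrix(1, 3, 4, dimnames = list(letters[1:3], LETTERS[1:4])),
    "normalized")
  expect_true(all(log_transform(ones, "10")$values == 0))
  expect_equal(log_transform(
    abundance_matrix(matrix(1000, 1, 1, dimnames = list("m", "s")),
                     "normalized"), "10")$values[1, 1], 3)

  withzero <- abundance_matrix(
    matrix(c(1, 0, 2, 3), 2, 2, dimnames = list(c("a", "b"), c("x", "y"))),
    "normalized")
  expect_error(log_transform(withzero), "\\(b, x\\)")
})

test_that("outlier flagging uses pooled quartiles and strict inequalities", {
  # constant matrix: Q1 = Q3 = median, nothing strictly outside
  const <- abundance_matrix(
    matrix(-5, 4, 6, dimnames = list(letters[1:4], LETTERS[1:6])), "log")
  rep <- flag_outlier_samples(const)
  expect_equal(nrow(rep$flagged), 0)
  expect_equal(rep$dataset_q1, rep$dataset_q3)

  # classification is strict: a median exactly at a quartile is kept
  expect_equal(classify_sample_medians(c(-8.02, -8.01, -6, -4.13, -4.12),
                                       q1 = -8.01, q3 = -4.13),
               c("below_q1", "ok", "ok", "ok", "above_q3"))

  # quartiles pool every non-missing measurement
  v <- random_matrix(15, 10, seed = 12, na_frac = 0.2, positive = FALSE)
  ab <- abundance_matrix(v, "log")
  rep <- flag_outlier_samples(ab)
  qs <- quantile(v[!is.na(v)], c(0.25, 0.75), names = FALSE)
  expect_equal(rep$dataset_q1, qs[1])
  expect_equal(rep$dataset_q3, qs[2])
  expect_equal(rep$sample_medians,
               apply(v, 2, median, na.rm = TRUE))
})

test_that("planted outlier samples are recovered exactly, and only when planted", {
  # a three-order-of-magnitude shift (the upper end of what the real
  # removed samples showed) clears the pooled quartiles decisively:
  # recovery is exact, with the planted direction
  for (s in c(2, 7)) {
    cfg <- simulation_config(seed = s,
                             outliers = list(n_samples = 8, log10_shift = 3))
    sim <- simulate_dataset(cfg)
    logged <- log_transform(normalize_abundance(sim$abundance, sim$meta))
    rep <- flag_outlier_samples(logged)
    expect_setequal(rep$flagged$sample_id, sim$truth$outlier_samples$sample_id)
    truth_dir <- setNames(sim$truth$outlier_samples$direction,
                          sim$truth$outlier_samples$sample_id)
    expect_equal(setNames(rep$flagged$direction, rep$flagged$sample_id),
                 truth_dir[rep$flagged$sample_id])
  }
  # at the default two-order shift a down-shifted sample can sit within a
  # quartile's sampling jitter of Q1, so the guarantee is no false
  # positives and recovery of the clearly shifted majority
  for (s in c(2, 7)) {
    sim <- simulate_dataset(simulation_config(seed = s))
    logged <- log_transform(normalize_abundance(sim$abundance, sim$meta))
    rep <- flag_outlier_samples(logged)
    expect_true(all(rep$flagged$sample_id %in%
                      sim$truth$outlier_samples$sample_id))
    expect_gte(nrow(rep$flagged), 5)
  }
  clean <- simulation_config(seed = 3,
                             outliers = list(n_samples = 0, log10_shift = 2))
  sim <- simulate_dataset(clean)
  logged <- log_transform(normalize_abundance(sim$abundance, sim$meta))
  expect_equal(nrow(flag_outlier_samples(logged)$flagged), 0)
})

test_that("PCA matches a direct eigendecomposition of the correlation matrix", {
  v <- random_matrix(10, 6, seed = 13, na_frac = 0, positive = FALSE)
  ab <- abundance_matrix(v, "log")
  pc <- pca_scores(ab, n_components = 5)
  # oracle: eigenvalues of the metabolite correlation matrix
  ev <- eigen(cor(t(v)), symmetric = TRUE)$values
  expect_equal(pc$explained_variance, (ev / sum(ev))[1:5], tolerance = 1e-8)
  expect_true(all(diff(pc$explained_variance) <= 1e-12))
  expect_lte(sum(pc$explained_variance), 1 + 1e-12)
})

test_that("rank-1 data put all variance on the first component", {
  s <- seq_len(8)
  v <- outer(c(1, -2, 0.5, 3), s) +
    matrix(rep(c(5, 1, 0, -2), 8), nrow = 4)
  dimnames(v) <- list(letters[1:4], paste0("s", s))
  pc <- pca_scores(abundance_matrix(v, "log"), 2)
  expect_equal(pc$explained_variance[1], 1, tolerance = 1e-10)
})

test_that("tissue structure dominates the leading PCA scores", {
  x <- simulate_qc(17)
  pc <- pca_scores(x$logged, 2)
  tissue <- x$meta$tissue[match(rownames(pc$scores), x$meta$sample_id)]
  # hand-rolled mean silhouette over the first two score dimensions
  d <- as.matrix(dist(pc$scores))
  sil <- vapply(seq_along(tissue), function(i) {
    a <- mean(d[i, tissue == tissue[i] & seq_along(tissue) != i])
    b <- mean(d[i, tissue != tissue[i]])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0)
})

test_that("metabolites that cannot be unit-scaled are excluded with a warning", {
  v <- random_matrix(5, 6, seed = 14, na_frac = 0, positive = FALSE)
  v[2, ] <- 4
  ab <- abundance_matrix(v, "log")
  expect_warning(pc <- pca_scores(ab, 2), "zero-variance")
  expect_true("met02" %in% pc$excluded_metabolites)
})
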