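two_group_fixture <- function(values_a, values_b) {
  # one metabolite, two genotypes at day 0, replicates as given
  na <- length(values_a)
  nb <- length(values_b)
  meta <- rbind(
    enumerate_design(genotypes = "WT", tissues = "root", regimes = "basal",
                     days = 0, replicates = seq_len(na)),
    enumerate_design(genotypes = "BRL3ox", tissues = "root", regimes = "basal",
                     days = 0, replicates = seq_len(nb))
  )
  meta$fresh_weight_mg <- 30
  v <- matrix(c(values_a, values_b), nrow = 1,
              dimnames = list("m1", meta$sample_id))
  list(ab = abundance_matrix(v, "log"), meta = meta)
}

test_that("identical groups give t = 0, p = 1 and zero fold-change", {
  x <- two_group_fixture(c(1, 2, 3), c(1, 2, 3))
  res <- compare_groups(x$ab, x$meta, "genotype", "WT", "BRL3ox")
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_equal(res$log_fc, 0)
  expect_false(res$significant)
})

test_that("pooled t statistic matches the closed form on the worked example", {
  x <- two_group_fixture(c(1, 2, 3), c(2, 3, 4))
  res <- compare_groups(x$ab, x$meta, "genotype", "WT", "BRL3ox")
  expect_equal(res$t, -1.224745, tolerance = 1e-6)
  expect_equal(res$df, 4)
  expect_equal(res$p, 0.2878641, tolerance = 1e-6)
  # oracle: the t CDF evaluated directly
  expect_equal(res$p, 2 * pt(-abs(res$t), 4), tolerance = 1e-12)
})

test_that("the t engine agrees with stats::t.test on random instances", {
  set.seed(42)
  for (i in 1:20) {
    na <- sample(2:8, 1)
    nb <- sample(2:8, 1)
    a <- rnorm(na)
    b <- rnorm(nb, mean = runif(1, -1, 1))
    x <- two_group_fixture(a, b)
    res <- compare_groups(x$ab, x$meta, "genotype", "WT", "BRL3ox")
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(res$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p, ref$p.value, tolerance = 1e-12)
    expect_equal(res$df, unname(ref$parameter))
  }
})

test_that("swapping the levels negates t and fold-change but keeps p", {
  x <- two_group_fixture(c(0.3, 1.1, 0.7, 1.9), c(2.5, 2.2, 3.0, 2.8))
  ab_first <- compare_groups(x$ab, x$meta, "genotype", "WT", "BRL3ox")
  ba_first <- compare_groups(x$ab, x$meta, "genotype", "BRL3ox", "WT")
  expect_equal(ab_first$t, -ba_first$t)
  expect_equal(ab_first$log_fc, -ba_first$log_fc)
  expect_equal(ab_first$p, ba_first$p)
})

test_that("null comparisons are calibrated near the nominal level", {
  set.seed(99)
  meta <- two_group_fixture(rnorm(5), rnorm(5))$meta
  v <- matrix(rnorm(1000 * 10), nrow = 1000,
              dimnames = list(sprintf("m%04d", 1:1000), meta$sample_id))
  res <- compare_groups(abundance_matrix(v, "log"), meta, "genotype",
                        "WT", "BRL3ox")
  frac <- mean(res$p < 0.025)
  expect_gte(frac, 0.015)
  expect_lte(frac, 0.035)
})

test_that("a planted basal accumulation is called significant", {
  # 3x accumulation in 6 of 30 metabolites, CV 0.2, n = 5 per group
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    meta <- two_group_fixture(rnorm(5), rnorm(5))$meta
    base <- rlnorm(30, sdlog = 2)
    v <- matrix(base, 30, 10) * rlnorm(300, sdlog = sqrt(log(1.04)))
    v[1:6, 6:10] <- v[1:6, 6:10] * 3
    dimnames(v) <- list(sprintf("m%02d", 1:30), meta$sample_id)
    res <- compare_groups(abundance_matrix(v, "normalized"), meta,
                          "genotype", "WT", "BRL3ox")
    if (all(res$significant[1:6]) ) hits <- hits + 1
    expect_true(all(res$log_fc[1:6] > 0))
  }
  expect_gte(hits, 9)
})

test_that("metabolites too sparse in a group are reported, not tested", {
  x <- two_group_fixture(c(1, 2, 3), c(2, 3, 4))
  v <- rbind(x$ab$values, m2 = c(NA, NA, 1, 4, 5, 6))
  res <- compare_groups(abundance_matrix(v, "log"), x$meta,
                        "genotype", "WT", "BRL3ox")
  expect_true(is.na(res$p[res$metabolite == "m2"]))
  expect_equal(attr(res, "not_tested"), "m2")
  expect_error(
    compare_groups(x$ab, x$meta, "genotype", "WT", "quad"),
    "at least 2 samples")
})

ratio_fixture <- function(seed = 1, replicates = 1:5) {
  meta <- enumerate_design(genotypes = "WT", regimes = c("basal", "drought"),
                           replicates = replicates)
  meta$fresh_weight_mg <- ifelse(meta$tissue == "shoot", 55, 30)
  v <- random_matrix(6, nrow(meta), seed = seed, na_frac = 0,
                     positive = FALSE)
  colnames(v) <- meta$sample_id
  list(ab = abundance_matrix(v, "log"), meta = meta)
}

test_that("shoot/root log-ratios obey identity and antisymmetry", {
  x <- ratio_fixture(2)
  # make shoot equal root for one metabolite
  shoot_ids <- x$meta$sample_id[x$meta$tissue == "shoot"]
  root_ids <- sub("_shoot_", "_root_", shoot_ids)
  v <- x$ab$values
  v[1, shoot_ids] <- v[1, root_ids]
  ab <- abundance_matrix(v, "log")
  rat <- shoot_root_ratios(ab, x$meta)
  expect_true(all(rat$log_ratios[1, ] == 0))
  # swapping tissue labels negates every ratio
  meta_swap <- x$meta
  meta_swap$tissue <- ifelse(x$meta$tissue == "shoot", "root", "shoot")
  rat_swap <- shoot_root_ratios(ab, meta_swap)
  expect_equal(rat_swap$log_ratios[, colnames(rat$log_ratios)],
               -rat$log_ratios)
})

test_that("discarding one tissue's replicate drops the pair and records it", {
  x <- ratio_fixture(3)
  drop_id <- x$meta$sample_id[x$meta$tissue == "shoot" &
                                x$meta$day == 3 & x$meta$replicate == 2]
  filt <- drop_samples(x$ab, x$meta, drop_id)
  rat <- shoot_root_ratios(filt$abundance, filt$meta)
  d3 <- rat$pairs[rat$pairs$day == 3 & rat$pairs$regime == "drought", ]
  expect_equal(nrow(d3), 4)
  expect_equal(nrow(rat$dropped_pairs), 1)
  expect_equal(rat$dropped_pairs$missing_tissue, "shoot")
})

test_that("comparing ratios equals testing the difference of log tissue values", {
  x <- ratio_fixture(4, replicates = 1:4)
  rat <- shoot_root_ratios(x$ab, x$meta)
  res_ratio <- compare_ratio_groups(rat, "day", 1, 6,
                                    at = list(regime = "drought"))
  # oracle: build the difference matrix by hand and run the same t-test
  pick <- function(day) {
    p <- rat$pairs[rat$pairs$day == day & rat$pairs$regime == "drought", ]
    x$ab$values[, p$shoot_sample, drop = FALSE] -
      x$ab$values[, p$root_sample, drop = FALSE]
  }
  manual <- droughtmet:::pooled_t_rows(pick(1), pick(6))
  expect_equal(res_ratio$t, manual$t, tolerance = 1e-12)
  expect_equal(res_ratio$p, manual$p, tolerance = 1e-12)
})

test_that("zero denominators yield missing ratios with a warning", {
  x <- ratio_fixture(5)
  v <- exp(x$ab$values)
  root1 <- x$meta$sample_id[x$meta$tissue == "root"][1]
  v[2, root1] <- 0
  expect_warning(
    rat <- shoot_root_ratios(abundance_matrix(v, "normalized"), x$meta),
    "undefined")
  pair1 <- rat$pairs$pair_id[rat$pairs$root_sample == root1]
  expect_true(is.na(rat$log_ratios[2, pair1]))
})
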