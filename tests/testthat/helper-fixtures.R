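# Shared fixture builders. Everything is generated in code; no stored data.

# A small labelled matrix with optional missing cells.
random_matrix <- function(n_met = 10, n_samp = 8, seed = 1, na_frac = 0,
                          positive = TRUE) {
  set.seed(seed)
  v <- matrix(if (positive) rlnorm(n_met * n_samp) else rnorm(n_met * n_samp),
              nrow = n_met,
              dimnames = list(sprintf("met%02d", seq_len(n_met)),
                              sprintf("s%02d", seq_len(n_samp))))
  if (na_frac > 0) {
    idx <- sample(length(v), round(na_frac * length(v)))
    v[idx] <- NA
  }
  v
}

# Metadata for a plain one-genotype design with constant fresh weight.
flat_meta <- function(genotypes = "WT", tissues = "root", replicates = 1:5,
                      fw = 30) {
  meta <- enumerate_design(genotypes = genotypes, tissues = tissues,
                           replicates = replicates)
  meta$fresh_weight_mg <- fw
  meta
}

# Log-state abundance matrix of pure white noise on the full design of
# `flat_meta()`: no planted structure of any kind.
white_noise_logged <- function(seed, n_met = 40, meta = flat_meta()) {
  set.seed(seed)
  v <- matrix(rnorm(n_met * nrow(meta)), nrow = n_met,
              dimnames = list(sprintf("M%02d", seq_len(n_met)),
                              meta$sample_id))
  abundance_matrix(v, state = "log")
}

# Default-conditions simulation run through normalization, log transform and
# outlier QC, as the analysis stages expect.
simulate_qc <- function(seed, config = simulation_config(seed = seed)) {
  config$seed <- as.integer(seed)
  sim <- simulate_dataset(config)
  logged <- log_transform(normalize_abundance(sim$abundance, sim$meta))
  rep <- flag_outlier_samples(logged)
  filt <- drop_samples(logged, sim$meta, rep$flagged$sample_id)
  list(logged = filt$abundance, meta = filt$meta, truth = sim$truth,
       outlier_report = rep)
}
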