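#' Default metabolite identifiers for simulated datasets
#'
#' The first entries are common GC-MS plant metabolites (so that planted
#' osmoprotectants and DNB members carry field-realistic names); the rest are
#' generic placeholders.
#'
#' @param n number of metabolite ids (internal standard not included).
#' @return character vector of length `n`.
#' @export
default_metabolite_ids <- function(n) {
  named <- c(
    "Raffinose", "Proline", "Galactinol", "Sucrose", "Galactose", "Maltose",
    "Fumarate", "Ornithine", "Glutamine", "Citrate", "Glucose", "Isocitrate",
    "Urea", "Glucose-6-Phosphate", "4-Hydroxyproline", "Fructose", "Myo-Inositol",
    "Alanine", "Serine", "Threonine", "Valine", "Leucine", "Isoleucine",
    "Glycine", "Aspartate", "Glutamate", "GABA", "Putrescine", "Succinate",
    "Malate", "Trehalose", "Xylose", "Arabinose", "Mannose", "Sorbitol",
    "Glycerol", "Shikimate", "Quinate", "Benzoate", "Phenylalanine"
  )
  if (n <= length(named)) return(named[seq_len(n)])
  c(named, sprintf("Metabolite_%03d", seq_len(n - length(named))))
}

#' Simulation configuration
#'
#' Defines the study conditions emulated by [simulate_dataset()]: the full
#' 3 genotypes x 2 tissues x (basal + 6 days x 2 regimes) x 5 replicates
#' design (390 samples), log-normal baseline abundances spanning several
#' orders of magnitude, an internal-standard row, drought-induced exponential
#' osmoprotectant accumulation that is steeper in BRL3ox, a planted DNB
#' cluster with inflated replicate variance and intra-correlation at a
#' critical day, and outlier samples with globally shifted medians.
#'
#' @param seed integer RNG seed.
#' @param n_metabolites number of metabolites (internal standard excluded).
#' @param genotypes,tissues,days,replicates design factors, as in
#'   [enumerate_design()] (all three regimes are always generated).
#' @param baseline_log10_range interval of per-metabolite baseline abundances
#'   on the log10 scale.
#' @param replicate_cv coefficient of variation of replicate noise on the
#'   natural scale.
#' @param tissue_effect_sd standard deviation (natural-log scale) of the
#'   per-metabolite shoot-vs-root abundance offset. Tissue of origin is the
#'   dominant structured factor in the emulated data (shoot and root
#'   metabolomes differ by up to orders of magnitude for many compounds),
#'   which is what makes samples separate by tissue in PCA diagnostics.
#' @param osmoprotectants list with `ids` (metabolite ids) and `rates`
#'   (named per-genotype exponential accumulation rates per day, drought
#'   series only; the watered series stays time-flat).
#' @param dnb list with `members` (>= 2 metabolite ids), `critical_day`
#'   (1..6), `sd_inflation` (> 1) and `intra_correlation` (in (0,1)): at the
#'   critical day of the drought series, member replicate noise is scaled by
#'   `sd_inflation` and given pairwise correlation `intra_correlation`
#'   through a shared latent factor (loading sqrt(intra_correlation)).
#' @param outliers list with `n_samples` and `log10_shift`: that many samples
#'   have every metabolite row (not the standard row, so the shift survives
#'   normalization, as an extraction artifact does) multiplied by
#'   `10^(+/- log10_shift)`, direction random per sample.
#' @param standard_id internal-standard metabolite id.
#' @param fresh_weight_mean_mg named vector of mean aliquot fresh weights,
#'   mg, per tissue (shoot 55, root 30).
#' @param fresh_weight_jitter_mg half-width of the uniform fresh-weight
#'   jitter (+/- 5 mg).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_metabolites = 60L,
                              genotypes = GENOTYPE_LEVELS,
                              tissues = TISSUE_LEVELS,
                              days = 0:6,
                              replicates = 1:5,
                              baseline_log10_range = c(-3, 3),
                              replicate_cv = 0.2,
                              tissue_effect_sd = 1.5,
                              osmoprotectants = list(
                                ids = c("Raffinose", "Proline", "Galactinol",
                                        "Sucrose", "Galactose", "Maltose"),
                                rates = c(WT = 0.3, BRL3ox = 0.7, quad = 0.3)
                              ),
                              dnb = list(
                                members = c("Fumarate", "Ornithine",
                                            "Glutamine", "Citrate"),
                                critical_day = 5L,
                                sd_inflation = 3,
                                intra_correlation = 0.8
                              ),
                              outliers = list(n_samples = 8L, log10_shift = 2),
                              standard_id = "Ribitol",
                              fresh_weight_mean_mg = c(shoot = 55, root = 30),
                              fresh_weight_jitter_mg = 5,
                              metabolite_ids = NULL) {
  if (is.null(metabolite_ids)) {
    metabolite_ids <- default_metabolite_ids(n_metabolites)
  }
  if (length(metabolite_ids) != n_metabolites) {
    stop("metabolite_ids must have length n_metabolites")
  }
  cfg <- structure(
    list(seed = as.integer(seed), n_metabolites = as.integer(n_metabolites),
         genotypes = genotypes, tissues = tissues, days = as.integer(days),
         replicates = as.integer(replicates),
         baseline_log10_range = baseline_log10_range,
         replicate_cv = replicate_cv, tissue_effect_sd = tissue_effect_sd,
         osmoprotectants = osmoprotectants,
         dnb = dnb, outliers = outliers, standard_id = standard_id,
         fresh_weight_mean_mg = fresh_weight_mean_mg,
         fresh_weight_jitter_mg = fresh_weight_jitter_mg,
         metabolite_ids = metabolite_ids),
    class = "simulation_config"
  )
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  if (length(cfg$baseline_log10_range) != 2 ||
      diff(cfg$baseline_log10_range) < 0) {
    stop("baseline_log10_range must be an interval")
  }
  if (cfg$replicate_cv <= 0) stop("replicate_cv must be positive")
  if (cfg$tissue_effect_sd < 0) stop("tissue_effect_sd must be non-negative")
  if (!is.null(cfg$osmoprotectants) && length(cfg$osmoprotectants$ids) > 0) {
    if (!all(cfg$osmoprotectants$ids %in% cfg$metabolite_ids)) {
      stop("osmoprotectant ids must be a subset of metabolite ids")
    }
    if (!all(cfg$genotypes %in% names(cfg$osmoprotectants$rates))) {
      stop("osmoprotectant rates must name every genotype")
    }
  }
  dnb <- cfg$dnb
  if (!is.null(dnb) && length(dnb$members) > 0) {
    if (length(dnb$members) < 2) {
      stop("dnb members must number at least 2 (pairwise correlation undefined)")
    }
    if (!all(dnb$members %in% cfg$metabolite_ids)) {
      stop("dnb member ids must be a subset of metabolite ids")
    }
    if (!dnb$critical_day %in% cfg$days[cfg$days >= 1]) {
      stop("dnb critical_day must be one of the timed days")
    }
    if (dnb$sd_inflation <= 1) stop("dnb sd_inflation must exceed 1")
    if (dnb$intra_correlation <= 0 || dnb$intra_correlation >= 1) {
      stop("dnb intra_correlation must lie in (0,1)")
    }
  }
  if (cfg$standard_id %in% cfg$metabolite_ids) {
    stop("standard_id must not collide with a metabolite id")
  }
  if (!all(cfg$tissues %in% names(cfg$fresh_weight_mean_mg))) {
    stop("fresh_weight_mean_mg must name every tissue")
  }
  invisible(cfg)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(list = ".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

#' Simulate a raw-peak dataset with ground truth
#'
#' Generates a raw peak-area matrix (internal-standard row included), sample
#' metadata, and the ground-truth labels needed for recovery tests. Peak
#' areas are `concentration x fresh_weight x detector_factor`, with the
#' per-sample detector factor drawn log-uniform in \[0.5, 2\] and applied to
#' every row including the standard, so that internal-standard plus
#' fresh-weight normalization cancels it exactly. Deterministic given the
#' seed.
#'
#' @param config a [simulation_config()].
#' @param seed optional seed overriding `config$seed`.
#' @return list with `abundance` (raw_peak [abundance_matrix()]), `meta`
#'   (sample metadata with fresh weights) and `truth` (ground-truth list:
#'   osmoprotectant ids/rates, DNB members/critical day, outlier sample ids
#'   and directions, per-metabolite baseline log10 means).
#' @export
simulate_dataset <- function(config = simulation_config(), seed = NULL) {
  validate_simulation_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  with_seed(config$seed, {
    meta <- enumerate_design(config$genotypes, config$tissues,
                             REGIME_LEVELS, config$days, config$replicates)
    S <- nrow(meta)
    fw_mean <- config$fresh_weight_mean_mg[meta$tissue]
    meta$fresh_weight_mg <- fw_mean +
      runif(S, -config$fresh_weight_jitter_mg, config$fresh_weight_jitter_mg)

    ids <- config$metabolite_ids
    M <- length(ids)
    baseline_log10 <- runif(M, config$baseline_log10_range[1],
                            config$baseline_log10_range[2])
    names(baseline_log10) <- ids
    sigma <- sqrt(log(1 + config$replicate_cv^2))  # log-scale noise SD

    log_conc <- matrix(log(10) * baseline_log10, nrow = M, ncol = S,
                       dimnames = list(ids, meta$sample_id))
    # shoot-vs-root metabolome divergence (root is the reference tissue)
    tissue_offset <- rnorm(M, sd = config$tissue_effect_sd)
    names(tissue_offset) <- ids
    log_conc <- log_conc + outer(tissue_offset,
                                 as.numeric(meta$tissue == "shoot"))
    eps <- matrix(rnorm(M * S, sd = sigma), nrow = M)

    # planted DNB: correlated, inflated replicate noise at the critical day
    dnb <- config$dnb
    if (!is.null(dnb) && length(dnb$members) > 0) {
      cols <- which(meta$regime == "drought" & meta$day == dnb$critical_day)
      m_idx <- match(dnb$members, ids)
      rho <- dnb$intra_correlation
      latent <- rnorm(length(cols))
      shared <- matrix(latent, nrow = length(m_idx), ncol = length(cols),
                       byrow = TRUE)
      idio <- matrix(rnorm(length(m_idx) * length(cols)),
                     nrow = length(m_idx))
      eps[m_idx, cols] <- dnb$sd_inflation * sigma *
        (sqrt(rho) * shared + sqrt(1 - rho) * idio)
    }

    # drought-only exponential osmoprotectant accumulation
    osmo <- config$osmoprotectants
    if (!is.null(osmo) && length(osmo$ids) > 0) {
      o_idx <- match(osmo$ids, ids)
      drought <- meta$regime == "drought"
      rate <- osmo$rates[meta$genotype]
      effect <- outer(rep(1, length(o_idx)),
                      ifelse(drought, rate * meta$day, 0))
      log_conc[o_idx, ] <- log_conc[o_idx, ] + effect
    }

    log_conc <- log_conc + eps
    detector <- exp(runif(S, log(0.5), log(2)))
    scale <- meta$fresh_weight_mg * detector
    peaks <- sweep(exp(log_conc), 2, scale, `*`)

    # internal standard: constant spiked amount, detector factor only
    standard_amount <- 1000
    std_row <- matrix(standard_amount * detector, nrow = 1,
                      dimnames = list(config$standard_id, meta$sample_id))
    values <- rbind(std_row, peaks)

    # outlier samples: global multiplicative shift of all metabolite rows
    out_spec <- config$outliers
    outlier_df <- data.frame(sample_id = character(), direction = character(),
                             stringsAsFactors = FALSE)
    if (!is.null(out_spec) && out_spec$n_samples > 0) {
      o_cols <- sample(S, out_spec$n_samples)
      sign <- sample(c(-1, 1), out_spec$n_samples, replace = TRUE)
      for (j in seq_along(o_cols)) {
        values[-1, o_cols[j]] <- values[-1, o_cols[j]] *
          10^(sign[j] * out_spec$log10_shift)
      }
      outlier_df <- data.frame(
        sample_id = meta$sample_id[o_cols],
        direction = ifelse(sign > 0, "above_q3", "below_q1"),
        stringsAsFactors = FALSE
      )
    }

    abund <- abundance_matrix(values, state = "raw_peak",
                              standard_id = config$standard_id)
    truth <- list(
      osmoprotectants = osmo,
      dnb = dnb[c("members", "critical_day", "sd_inflation",
                  "intra_correlation")],
      outlier_samples = outlier_df,
      baseline_log10 = baseline_log10,
      tissue_offset = tissue_offset,
      detector_factor = setNames(detector, meta$sample_id),
      seed = config$seed
    )
    list(abundance = abund, meta = meta, truth = truth)
  })
}
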