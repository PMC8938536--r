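#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Per-stage sections hold the
#' tunables of each analysis; only the stages listed in `stages` run.
#'
#' @param matrix_path,meta_path input raw-peak matrix and sample metadata.
#' @param out_dir output directory (created if absent).
#' @param standard_id internal-standard row id.
#' @param log_base log base for the transform ("e", "10" or "2").
#' @param alpha raw-p threshold for pairwise comparisons (default 0.025).
#' @param stages character vector of stages to run, from `normalize`, `qc`,
#'   `pca`, `compare`, `ratios`, `dynamics`, `dnb`, `integrate`.
#' @param comparisons list of comparison specs for the `compare` stage, each
#'   `list(factor=, a=, b=, at=)`.
#' @param dynamics list: `tissue`, `series`, `degree`, `reference`,
#'   `q_threshold`, `r2_min`, `clusters` (optional k).
#' @param dnb list: `genotype`, `tissue`, `k`, `min_size`.
#' @param integrate list: `gene_hits`, `gene_universe`, `met_hits`,
#'   `met_universe` (files, one id per line), `annotation` (annotation TSV).
#' @param seed integer seed recorded in output provenance.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(matrix_path, meta_path, out_dir,
                            standard_id = "Ribitol", log_base = "e",
                            alpha = 0.025,
                            stages = c("normalize", "qc", "pca"),
                            comparisons = list(),
                            dynamics = list(tissue = "root",
                                            series = "drought", degree = 2,
                                            reference = "WT",
                                            q_threshold = 0.05, r2_min = 0.6),
                            dnb = list(genotype = "WT", tissue = "root",
                                       k = 10, min_size = 2),
                            integrate = NULL,
                            seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0,1)")
  if (!log_base %in% c("e", "10", "2")) stop("log_base must be e, 10 or 2")
  known <- c("normalize", "qc", "pca", "compare", "ratios", "dynamics",
             "dnb", "integrate")
  if (!all(stages %in% known)) {
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  }
  if (!is.null(dynamics)) {
    if (dynamics$q_threshold < 0 || dynamics$q_threshold > 1) {
      stop("dynamics q_threshold must lie in [0,1]")
    }
    if (dynamics$r2_min < 0 || dynamics$r2_min > 1) {
      stop("dynamics r2_min must lie in [0,1]")
    }
  }
  structure(
    list(matrix_path = matrix_path, meta_path = meta_path, out_dir = out_dir,
         standard_id = standard_id, log_base = log_base, alpha = alpha,
         stages = stages, comparisons = comparisons, dynamics = dynamics,
         dnb = dnb, integrate = integrate, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path config file; top-level keys as in [pipeline_config()].
#' @return object of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(pipeline_config, cfg)
}

config_hash <- function(config) {
  # hash the analysis-relevant configuration; where outputs land does not
  # change what was computed
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(json, tf)
  unname(tools::md5sum(tf))
}

provenance_header <- function(config) {
  c(sprintf("# droughtmet %s", as.character(packageVersion("droughtmet"))),
    sprintf("# seed: %d", config$seed),
    sprintf("# config_hash: %s", config_hash(config)))
}

write_stage_table <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(config), con)
  write.table(format(df, digits = 15, trim = TRUE, scientific = NA),
              con, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Run the analysis pipeline end to end
#'
#' Reads the raw-peak matrix and metadata, normalizes, log-transforms,
#' removes QC-flagged outlier samples, and runs the configured downstream
#' stages, writing one TSV/JSON artifact per stage into the output
#' directory. Every artifact carries a provenance header (package version,
#' seed, config hash); identical config and seed give identical outputs.
#' Any stage failure aborts with a stage-named error.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the written file paths and the in-memory
#'   stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  loaded <- stage("read", read_abundance(config$matrix_path, config$meta_path,
                                         standard_id = config$standard_id))
  abund <- loaded$abundance
  meta <- loaded$meta
  results <- list()

  norm <- stage("normalize",
                normalize_abundance(abund, meta, config$standard_id))
  logged <- stage("normalize", log_transform(norm, config$log_base))
  if ("normalize" %in% config$stages) {
    p <- file.path(config$out_dir, "normalized.tsv")
    con <- file(p, "w")
    writeLines(provenance_header(config), con)
    close(con)
    tf <- tempfile()
    write_abundance(norm, tf)
    file.append(p, tf)
    unlink(tf)
    written <- c(written, p)
  }

  if ("qc" %in% config$stages) {
    rep <- stage("qc", flag_outlier_samples(logged))
    results$qc <- rep
    p <- file.path(config$out_dir, "qc_outliers.tsv")
    qc_df <- data.frame(sample_id = names(rep$sample_medians),
                        log_median = unname(rep$sample_medians),
                        direction = classify_sample_medians(
                          rep$sample_medians, rep$dataset_q1, rep$dataset_q3),
                        stringsAsFactors = FALSE)
    write_stage_table(qc_df, p, config)
    pj <- file.path(config$out_dir, "qc_outliers.json")
    jsonlite::write_json(
      list(dataset_median = rep$dataset_median, q1 = rep$dataset_q1,
           q3 = rep$dataset_q3, flagged = rep$flagged),
      pj, auto_unbox = TRUE, digits = NA)
    written <- c(written, p, pj)
    if (nrow(rep$flagged) > 0) {
      filt <- stage("qc", drop_samples(logged, meta, rep$flagged$sample_id))
      logged <- filt$abundance
      meta <- filt$meta
      results$not_identified <- filt$not_identified
    }
  }

  if ("pca" %in% config$stages) {
    pca <- stage("pca", pca_scores(logged, n_components = 2))
    results$pca <- pca
    p <- file.path(config$out_dir, "pca_scores.tsv")
    df <- data.frame(sample_id = rownames(pca$scores), pca$scores,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_stage_table(df, p, config)
    written <- c(written, p)
  }

  if ("compare" %in% config$stages) {
    for (i in seq_along(config$comparisons)) {
      cmp <- config$comparisons[[i]]
      res <- stage("compare",
                   compare_groups(logged, meta, cmp$factor, cmp$a, cmp$b,
                                  at = cmp$at, alpha = config$alpha))
      results$comparisons[[i]] <- res
      p <- file.path(config$out_dir,
                     sprintf("compare_%s_%s_vs_%s.tsv", cmp$factor, cmp$a,
                             cmp$b))
      write_stage_table(as.data.frame(res), p, config)
      written <- c(written, p)
    }
  }

  if ("ratios" %in% config$stages) {
    rat <- stage("ratios", shoot_root_ratios(logged, meta))
    results$ratios <- rat
    p <- file.path(config$out_dir, "shoot_root_ratios.tsv")
    df <- data.frame(metabolite = rownames(rat$log_ratios), rat$log_ratios,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_stage_table(df, p, config)
    written <- c(written, p)
  }

  if ("dynamics" %in% config$stages) {
    dyn <- config$dynamics
    fits <- stage("dynamics",
                  fit_time_course(logged, meta, tissue = dyn$tissue,
                                  degree = dyn$degree,
                                  reference_genotype = dyn$reference,
                                  series = dyn$series))
    selected <- select_differential(fits, dyn$q_threshold, dyn$r2_min)
    results$dynamics <- list(fits = fits, selected = selected)
    p <- file.path(config$out_dir, "dynamics_fits.tsv")
    write_stage_table(as.data.frame(fits), p, config)
    written <- c(written, p)
    if (!is.null(dyn$clusters) && length(selected) >= dyn$clusters) {
      cl <- stage("dynamics",
                  cluster_profiles(logged, meta, selected, dyn$clusters,
                                   tissue = dyn$tissue, series = dyn$series))
      results$dynamics$clusters <- cl
      p <- file.path(config$out_dir, "dynamics_clusters.tsv")
      write_stage_table(data.frame(metabolite = names(cl), cluster = cl),
                        p, config)
      written <- c(written, p)
    }
  }

  if ("dnb" %in% config$stages) {
    d <- config$dnb
    res <- stage("dnb", detect_dnb(logged, meta, d$genotype, d$tissue,
                                   k_clusters = d$k,
                                   min_cluster_size = d$min_size))
    results$dnb <- res
    p <- file.path(config$out_dir, "dnb_stats.tsv")
    write_stage_table(res$stats, p, config)
    pj <- file.path(config$out_dir, "dnb_result.json")
    jsonlite::write_json(
      list(critical_point = res$critical_point,
           dnb_members = res$dnb_members),
      pj, auto_unbox = TRUE, digits = NA)
    written <- c(written, p, pj)
  }

  if ("integrate" %in% config$stages) {
    it <- config$integrate
    if (is.null(it)) stop("stage 'integrate' failed: no integrate config")
    res <- stage("integrate", integrate_pathways(
      readLines(it$gene_hits), readLines(it$gene_universe),
      readLines(it$met_hits), readLines(it$met_universe),
      read_pathway_annotation(it$annotation)))
    results$integration <- res
    p <- file.path(config$out_dir, "pathway_integration.tsv")
    write_stage_table(as.data.frame(res), p, config)
    written <- c(written, p)
  }

  invisible(list(written = written, results = results, config = config))
}
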