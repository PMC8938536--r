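#' One-sided hypergeometric over-representation p-value
#'
#' Probability of observing at least `n_selected_in_set` members of an
#' annotated set among `n_selected` draws from a universe of size
#' `n_universe` containing `n_set` set members (Fisher's exact test,
#' upper tail).
#'
#' @param n_selected_in_set overlap between the hit list and the set.
#' @param n_selected size of the hit list.
#' @param n_set size of the annotated set within the universe.
#' @param n_universe size of the universe.
#' @return the upper-tail hypergeometric probability, in (0, 1].
#' @export
overrepresentation_p <- function(n_selected_in_set, n_selected, n_set,
                                 n_universe) {
  k <- as.integer(n_selected_in_set)
  n <- as.integer(n_selected)
  m <- as.integer(n_set)
  N <- as.integer(n_universe)
  if (any(c(k, n, m, N) < 0)) stop("counts must be non-negative")
  if (k > min(n, m)) stop("overlap exceeds the hit list or the set")
  if (n > N || m > N) stop("hit list and set must fit in the universe")
  phyper(k - 1, m, N - m, n, lower.tail = FALSE)
}

#' Fisher's combined probability test
#'
#' Combines independent p-values via `X = -2 * sum(log(p))` referred to a
#' chi-square distribution with `2 * length(p)` degrees of freedom.
#'
#' @param pvalues numeric vector of p-values, each in (0, 1].
#' @return combined p-value in (0, 1].
#' @examples
#' fisher_combine(c(6.98e-4, 1.93e-2)) # 1.64e-4 at the printed precision
#' @export
fisher_combine <- function(pvalues) {
  if (length(pvalues) < 1) stop("need at least one p-value")
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  x <- -2 * sum(log(pvalues))
  pchisq(x, df = 2 * length(pvalues), lower.tail = FALSE)
}

#' Read a pathway annotation table
#'
#' @param path TSV/CSV file with columns `pathway_id`, `feature_id`,
#'   `feature_type` (`gene` or `metabolite`).
#' @return validated annotation data.frame.
#' @export
read_pathway_annotation <- function(path) {
  ann <- read.delim(path, sep = sep_for(path), check.names = FALSE,
                    stringsAsFactors = FALSE)
  need <- c("pathway_id", "feature_id", "feature_type")
  missing_cols <- setdiff(need, names(ann))
  if (length(missing_cols) > 0) {
    stop(paste(missing_cols, collapse = ", "), " required")
  }
  if (!all(ann$feature_type %in% c("gene", "metabolite"))) {
    stop("feature_type must be 'gene' or 'metabolite'")
  }
  ann
}

#' Pathway-level integration of gene and metabolite hits
#'
#' Per pathway, computes a hypergeometric over-representation p-value for
#' the differentially expressed genes and one for the differentially
#' accumulated metabolites (an omic with no annotated members in the
#' pathway, restricted to its universe, enters as p = 1), then merges the
#' two with Fisher's combined probability test. Duplicated identifiers are
#' counted once. Pathways with no annotated genes and no annotated
#' metabolites are skipped with a record.
#'
#' @param gene_hits,gene_universe character vectors of differential and
#'   measured gene ids (`gene_hits` must be a subset of `gene_universe`).
#' @param met_hits,met_universe same for metabolites.
#' @param annotation data.frame with columns `pathway_id`, `feature_id`,
#'   `feature_type` (see [read_pathway_annotation()]).
#' @return data.frame of class `pathway_integration`, sorted by combined
#'   p-value: pathway, unique gene/metabolite hit counts, `p_genes`,
#'   `p_metabolites`, `p_combined`; attribute `skipped_pathways`.
#' @export
integrate_pathways <- function(gene_hits, gene_universe, met_hits,
                               met_universe, annotation) {
  gene_hits <- unique(as.character(gene_hits))
  met_hits <- unique(as.character(met_hits))
  gene_universe <- unique(as.character(gene_universe))
  met_universe <- unique(as.character(met_universe))
  if (!all(gene_hits %in% gene_universe)) {
    stop("gene hits must be a subset of the gene universe")
  }
  if (!all(met_hits %in% met_universe)) {
    stop("metabolite hits must be a subset of the metabolite universe")
  }
  need <- c("pathway_id", "feature_id", "feature_type")
  if (!all(need %in% names(annotation))) {
    stop("annotation must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(annotation) == 0) stop("annotation is empty")

  pathways <- unique(annotation$pathway_id)
  rows <- list()
  skipped <- character()
  for (pw in pathways) {
    ann <- annotation[annotation$pathway_id == pw, , drop = FALSE]
    genes <- intersect(unique(ann$feature_id[ann$feature_type == "gene"]),
                       gene_universe)
    mets <- intersect(unique(ann$feature_id[ann$feature_type == "metabolite"]),
                      met_universe)
    if (length(genes) == 0 && length(mets) == 0) {
      skipped <- c(skipped, pw)
      next
    }
    g_overlap <- length(intersect(gene_hits, genes))
    m_overlap <- length(intersect(met_hits, mets))
    p_g <- if (length(genes) == 0) 1 else {
      overrepresentation_p(g_overlap, length(gene_hits), length(genes),
                           length(gene_universe))
    }
    p_m <- if (length(mets) == 0) 1 else {
      overrepresentation_p(m_overlap, length(met_hits), length(mets),
                           length(met_universe))
    }
    rows[[length(rows) + 1]] <- data.frame(
      pathway = pw, unique_genes = g_overlap, unique_metabolites = m_overlap,
      p_genes = p_g, p_metabolites = p_m,
      p_combined = fisher_combine(c(p_g, p_m)),
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) stop("no pathway with usable annotation")
  res <- do.call(rbind, rows)
  res <- res[order(res$p_combined, res$pathway), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("pathway_integration", "data.frame"),
            skipped_pathways = skipped)
}
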