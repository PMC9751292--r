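#' Cld genes per million genes
#'
#' Normalises a count of *cld* genes by the total gene count of an
#' environment, expressed per 10^6 genes. This is the biomarker-frequency
#' metric used to compare habitats of very different sampling depth.
#'
#' @param n_cld Number of *cld* genes observed (non-negative).
#' @param n_genes Total number of genes sampled (positive).
#' @return Rate of *cld* per million genes (numeric, vectorised).
#' @examples
#' cld_per_million(5, 1e7) # 0.5
#' @export
cld_per_million <- function(n_cld, n_genes) {
  if (any(n_genes <= 0)) {
    cld_abort("`n_genes` must be positive; cannot compute a rate over zero genes.",
              "division_error")
  }
  if (any(n_cld < 0)) {
    cld_abort("`n_cld` must be non-negative.", "parameter_error")
  }
  n_cld / n_genes * 1e6
}

#' Estimated percent of genomes encoding Cld
#'
#' Converts a gene frequency (per million genes) into an estimated percentage
#' of genomes encoding the gene, assuming a fixed average genome size in
#' genes. With the default 5000 genes per bacterial genome, a frequency of
#' 1 *cld* per million genes corresponds to roughly 0.5% of genomes.
#'
#' @param rate Gene frequency per million genes (non-negative).
#' @param genes_per_genome Average number of genes per genome (default 5000).
#' @return Estimated percent of genomes (numeric, vectorised).
#' @examples
#' percent_genomes(1) # 0.5
#' @export
percent_genomes <- function(rate, genes_per_genome = 5000) {
  if (any(genes_per_genome <= 0)) {
    cld_abort("`genes_per_genome` must be positive.", "parameter_error")
  }
  if (any(rate < 0)) {
    cld_abort("`rate` must be non-negative.", "parameter_error")
  }
  rate * genes_per_genome / 1e6 * 100
}

#' Per-environment Cld frequency table
#'
#' Computes, for each environment, the *cld*-per-million-genes rate and the
#' estimated percent of genomes encoding Cld, and flags environments that
#' pass the sample-size filter (strictly more than 10 million genes).
#'
#' @param counts Data frame with columns `environment`, `n_genes`, `n_cld`.
#' @param genes_per_genome Average genes per genome used for the conversion.
#' @param min_genes Sample-size filter; environments are `included` only when
#'   `n_genes` strictly exceeds this (default 10^7).
#' @return A tibble with columns `environment`, `n_genes`, `n_cld`,
#'   `cld_per_million`, `est_percent_genomes`, `included`.
#' @export
environment_frequency <- function(counts, genes_per_genome = 5000,
                                  min_genes = 1e7) {
  required <- c("environment", "n_genes", "n_cld")
  missing <- setdiff(required, names(counts))
  if (length(missing) > 0) {
    cld_abort(paste0("`counts` is missing column(s): ",
                     paste(missing, collapse = ", ")), "parameter_error")
  }
  counts %>%
    as_tibble() %>%
    dplyr::mutate(
      cld_per_million = cld_per_million(.data$n_cld, .data$n_genes),
      est_percent_genomes = percent_genomes(.data$cld_per_million,
                                            genes_per_genome),
      included = .data$n_genes > min_genes
    )
}
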