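#' Parse a HMMER tabular search output
#'
#' Reads the whitespace-delimited per-target (`tblout`) or per-domain
#' (`domtblout`) tables written by hmmsearch/hmmscan `--tblout` /
#' `--domtblout`, keeping the target, query model, full-sequence E-value
#' and bit score of every hit. Lines starting with `#` are comments.
#'
#' @param path Path to the table.
#' @param dialect `"tblout"` (default) or `"domtblout"`.
#' @param protein_genomes Optional data frame mapping `protein_id` to
#'   `genome_id`; when supplied, a `genome_id` column is joined on.
#' @return Tibble with columns `protein_id`, `query`, `evalue`, `score`
#'   (and `genome_id` when a map is supplied).
#' @export
parse_hmm_table <- function(path, dialect = c("tblout", "domtblout"),
                            protein_genomes = NULL) {
  dialect <- match.arg(dialect)
  # minimum data fields before the free-text description column
  n_min <- if (dialect == "tblout") 18L else 22L
  evalue_col <- if (dialect == "tblout") 5L else 7L
  score_col <- if (dialect == "tblout") 6L else 8L
  query_col <- if (dialect == "tblout") 3L else 4L

  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  bad <- which(lengths(fields) < n_min)
  if (length(bad) > 0) {
    cld_abort(paste0("Malformed ", dialect, " line ", rows[bad[1]], " in '",
                     path, "': expected at least ", n_min, " fields."),
              "parse_error")
  }
  evalue <- suppressWarnings(
    as.numeric(vapply(fields, `[[`, character(1), evalue_col)))
  score <- suppressWarnings(
    as.numeric(vapply(fields, `[[`, character(1), score_col)))
  if (any(is.na(evalue)) || any(is.na(score))) {
    bad <- which(is.na(evalue) | is.na(score))[1]
    cld_abort(paste0("Malformed ", dialect, " line ", rows[bad], " in '",
                     path, "': non-numeric E-value or score."),
              "parse_error")
  }
  hits <- tibble(
    protein_id = vapply(fields, `[[`, character(1), 1L),
    query = vapply(fields, `[[`, character(1), query_col),
    evalue = evalue,
    score = score
  )
  if (any(hits$evalue < 0)) {
    cld_abort("Negative E-value in HMM table.", "parse_error")
  }
  if (!is.null(protein_genomes)) {
    hits <- dplyr::left_join(hits,
                             as_tibble(protein_genomes)[, c("protein_id",
                                                            "genome_id")],
                             by = "protein_id")
  }
  hits
}

#' Screen Cld-encoding genomes for (per)chlorate-reductase co-presence
#'
#' Classifies genomes by the joint presence of Cld and of DMSO-reductase
#' family enzymes with putative perchlorate/chlorate reductase activity
#' (PCRA). A genome encoding Cld but no passing reductase hit is a
#' candidate non-(per)chlorate reducer: its chlorite must come from a
#' source other than enzymatic (per)chlorate reduction.
#'
#' @param cld_by_genome Data frame with columns `genome_id` and `has_cld`
#'   (logical); list every screened genome here, with or without Cld.
#' @param hits HMM hits with `genome_id` and `evalue` columns (see
#'   [parse_hmm_table()]).
#' @param evalue_cutoff Full-sequence E-value below which a hit counts
#'   (default 1e-5; must be positive).
#' @return A tibble with `genome_id`, `has_cld`, `has_pcra`, and
#'   `classification` in `{"non_perchlorate_reducer", "potential_reducer",
#'   "no_cld"}`; the cutoff is recorded as an attribute.
#' @export
classify_genomes <- function(cld_by_genome, hits, evalue_cutoff = 1e-5) {
  if (!is.numeric(evalue_cutoff) || evalue_cutoff <= 0) {
    cld_abort("`evalue_cutoff` must be positive.", "parameter_error")
  }
  cld_by_genome <- as_tibble(cld_by_genome)
  passing <- hits %>%
    as_tibble() %>%
    dplyr::filter(.data$evalue <= evalue_cutoff) %>%
    dplyr::distinct(.data$genome_id)
  out <- cld_by_genome %>%
    dplyr::mutate(
      has_pcra = .data$genome_id %in% passing$genome_id,
      classification = dplyr::case_when(
        !.data$has_cld ~ "no_cld",
        .data$has_cld & !.data$has_pcra ~ "non_perchlorate_reducer",
        TRUE ~ "potential_reducer"
      )
    )
  attr(out, "evalue_cutoff") <- evalue_cutoff
  out
}
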