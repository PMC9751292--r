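GENE_TABLE_COLS <- c("gene_id", "protein_id", "contig_id", "genome_id",
                     "start", "end", "strand", "genus", "phylum", "source")

#' Read a gene table from GFF3 or TSV
#'
#' Reads per-gene records and assigns each gene a 0-based ordinal index
#' along its contig, the coordinate system in which genomic neighborhoods
#' are defined. Within a contig, genes are ordered by (start, end, gene_id).
#'
#' For GFF3 only CDS features are used; the `ID` attribute becomes
#' `gene_id` and the attributes `protein_id`, `genome_id`, `genus`,
#' `phylum` and `sample_source` are carried through when present.
#' Coordinates are 1-based inclusive in both dialects.
#'
#' @param path Path to the file.
#' @param format `"gff3"` or `"tsv"` (header-bearing, columns `gene_id`,
#'   `protein_id`, `contig_id`, `genome_id`, `start`, `end`, `strand`,
#'   `genus`, `phylum`, `source`). Defaults from the file extension.
#' @return A tibble of gene records sorted and indexed per contig, with an
#'   integer `index` column (0-based, contiguous within each contig).
#' @export
read_gene_table <- function(path, format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  }
  genes <- if (format == "gff3") read_gene_gff3(path) else read_gene_tsv(path)
  index_gene_table(genes)
}

read_gene_gff3 <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) cld_abort(
      paste0("Failed to parse GFF3 '", path, "': ", conditionMessage(e)),
      "parse_error")
  )
  gr <- gr[!is.na(gr$type) & gr$type == "CDS"]
  mc <- as.data.frame(S4Vectors::mcols(gr))
  get_col <- function(nm) {
    if (nm %in% names(mc)) as.character(mc[[nm]]) else NA_character_
  }
  tibble(
    gene_id = get_col("ID"),
    protein_id = get_col("protein_id"),
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    genome_id = get_col("genome_id"),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    genus = get_col("genus"),
    phylum = get_col("phylum"),
    source = get_col("sample_source")
  )
}

read_gene_tsv <- function(path) {
  genes <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    protein_id = readr::col_character(),
    contig_id = readr::col_character(),
    genome_id = readr::col_character(),
    start = readr::col_integer(),
    end = readr::col_integer(),
    strand = readr::col_character(),
    .default = readr::col_character()
  ))
  probs <- readr::problems(genes)
  if (nrow(probs) > 0) {
    cld_abort(paste0("Malformed line ", probs$row[1], " in '", path, "': ",
                     probs$expected[1]), "parse_error")
  }
  missing <- setdiff(c("gene_id", "protein_id", "contig_id", "start", "end",
                       "strand"), names(genes))
  if (length(missing) > 0) {
    cld_abort(paste0("Gene table is missing column(s): ",
                     paste(missing, collapse = ", ")), "parse_error")
  }
  genes
}

# Sort within contig by (start, end, gene_id) and assign 0-based indices.
index_gene_table <- function(genes) {
  genes <- as_tibble(genes)
  if (nrow(genes) == 0) {
    genes$index <- integer(0)
    return(genes)
  }
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0) {
    cld_abort(paste0("Duplicate gene_id: ", dup[1]), "uniqueness_error")
  }
  if (any(genes$start > genes$end)) {
    bad <- genes$gene_id[which(genes$start > genes$end)[1]]
    cld_abort(paste0("Gene ", bad, " has start > end."), "parse_error")
  }
  genes %>%
    dplyr::arrange(.data$contig_id, .data$start, .data$end, .data$gene_id) %>%
    dplyr::group_by(.data$contig_id) %>%
    dplyr::mutate(index = dplyr::row_number() - 1L) %>%
    dplyr::ungroup()
}

#' Extract genomic neighborhoods around anchor genes
#'
#' For each anchor gene, collects the genes within `radius` ordinal
#' positions on the same contig (the anchor plus up to `radius` genes on
#' each side), truncating at contig boundaries. Offsets are strand-agnostic
#' contig positions relative to the anchor (offset 0). Neighborhoods whose
#' member gene sets are identical are deduplicated, keeping the first
#' anchor in input order.
#'
#' @param genes An indexed gene table from [read_gene_table()] (or any data
#'   frame with the same columns, including `index`).
#' @param anchor_ids Character vector of anchor `gene_id`s (the *cld*
#'   genes).
#' @param radius Window half-width in gene positions (default 10).
#' @return A tibble with one row per neighborhood member: `neighborhood_id`,
#'   `anchor_gene_id`, `contig_id`, `offset` (in `[-radius, radius]`,
#'   strictly increasing within a neighborhood), `gene_id`, `protein_id`,
#'   and `genome_id` when available.
#' @export
extract_neighborhoods <- function(genes, anchor_ids, radius = 10L) {
  genes <- as_tibble(genes)
  if (!"index" %in% names(genes)) genes <- index_gene_table(genes)
  if (!is_count(radius) || radius < 1) {
    cld_abort("`radius` must be a positive integer.", "parameter_error")
  }
  unknown <- setdiff(anchor_ids, genes$gene_id)
  if (length(unknown) > 0) {
    cld_abort(paste0("Anchor gene(s) not in the gene table: ",
                     paste(utils::head(unknown, 5), collapse = ", ")),
              "lookup_error")
  }
  by_contig <- split(genes, genes$contig_id)
  rows <- purrr::map(anchor_ids, function(aid) {
    anchor <- genes[genes$gene_id == aid, ]
    contig <- by_contig[[anchor$contig_id]]
    contig <- contig[order(contig$index), ]
    lo <- max(0L, anchor$index - radius)
    hi <- min(max(contig$index), anchor$index + radius)
    members <- contig[contig$index >= lo & contig$index <= hi, ]
    tibble(
      anchor_gene_id = aid,
      contig_id = anchor$contig_id,
      offset = members$index - anchor$index,
      gene_id = members$gene_id,
      protein_id = members$protein_id,
      genome_id = if ("genome_id" %in% names(members))
        members$genome_id else NA_character_
    )
  })
  # Deduplicate identical member gene sets, keeping the first anchor.
  keys <- vapply(rows, function(r) paste(sort(r$gene_id), collapse = "\r"),
                 character(1))
  rows <- rows[!duplicated(keys)]
  out <- purrr::imap_dfr(rows, function(r, i) {
    r$neighborhood_id <- paste0("nbh_", i)
    r
  })
  dplyr::relocate(out, "neighborhood_id")
}

#' Write / read neighborhoods as TSV
#'
#' @param neighborhoods A tibble from [extract_neighborhoods()].
#' @param path Output path.
#' @return `path`, invisibly (writer); a tibble (reader).
#' @export
write_neighborhoods <- function(neighborhoods, path) {
  readr::write_tsv(neighborhoods, path)
  invisible(path)
}

#' @rdname write_neighborhoods
#' @export
read_neighborhoods <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    offset = readr::col_integer(),
    .default = readr::col_character()
  ))
}
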