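#' Default catalytic key-residue specification for Cld
#'
#' The four residues jointly required for chlorite dismutase activity,
#' numbered on the ungapped reference sequence of *Nitrobacter winogradskyi*
#' Nb-255: the proximal heme lysine (K92), histidine (H114), the distal heme
#' arginine (R127), and glutamic acid (E167). Positions are 1-based on the
#' ungapped reference.
#'
#' @param reference_id Identifier of the reference sequence in the alignment.
#' @return A `key_residue_spec`: a tibble with columns `position` (strictly
#'   increasing) and `aa`, plus a `reference_id` attribute.
#' @export
default_key_residues <- function(reference_id) {
  key_residue_spec(reference_id,
                   positions = c(92L, 114L, 127L, 167L),
                   aas = c("K", "H", "R", "E"))
}

AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Build a key-residue specification
#'
#' @param reference_id Identifier of the reference sequence.
#' @param positions Integer vector of 1-based ungapped reference positions,
#'   strictly increasing.
#' @param aas Character vector of expected amino acids (single letters from
#'   the 20-letter alphabet), same length as `positions`.
#' @return A `key_residue_spec` tibble.
#' @export
key_residue_spec <- function(reference_id, positions, aas) {
  if (length(positions) != length(aas) || length(positions) == 0) {
    cld_abort("`positions` and `aas` must be non-empty and the same length.",
              "parameter_error")
  }
  if (any(diff(positions) <= 0)) {
    cld_abort("Key-residue positions must be strictly increasing.",
              "parameter_error")
  }
  aas <- toupper(aas)
  if (!all(aas %in% AA_ALPHABET20)) {
    cld_abort("Expected amino acids must be in the 20-letter alphabet.",
              "parameter_error")
  }
  out <- tibble(position = as.integer(positions), aa = aas)
  attr(out, "reference_id") <- reference_id
  class(out) <- c("key_residue_spec", class(out))
  out
}

# Normalise an alignment to a named character vector of equal-width strings.
as_alignment <- function(alignment) {
  if (inherits(alignment, "AAStringSet") || inherits(alignment, "XStringSet")) {
    alignment <- stats::setNames(as.character(alignment), names(alignment))
  }
  if (!is.character(alignment) || is.null(names(alignment))) {
    cld_abort("`alignment` must be a named character vector or an AAStringSet.",
              "parameter_error")
  }
  if (length(unique(nchar(alignment))) > 1) {
    cld_abort("Aligned sequences must all have the same width.",
              "format_error")
  }
  alignment
}

#' Read an aligned FASTA file
#'
#' @param path Path to an aligned FASTA file.
#' @return Named character vector of aligned sequences.
#' @export
read_alignment <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  as_alignment(seqs)
}

aln_matrix <- function(alignment, ids = names(alignment)) {
  m <- do.call(rbind, strsplit(toupper(unname(alignment[ids])), ""))
  rownames(m) <- ids
  m
}

is_gap <- function(chars) chars %in% c("-", ".")

#' Map reference key residues to alignment columns
#'
#' Resolves each 1-based ungapped position on the reference sequence to the
#' alignment column holding it, verifying that the reference carries the
#' expected amino acid there.
#'
#' @param alignment Named character vector (or AAStringSet) of aligned
#'   sequences, including the reference.
#' @param spec A [key_residue_spec()]; defaults to the canonical four Cld
#'   residues on `reference_id`.
#' @param reference_id Reference sequence identifier; defaults to the spec's
#'   `reference_id` attribute.
#' @return A `residue_map`: tibble with columns `position`, `aa`, `column`
#'   (1-based alignment column, strictly increasing), with a `reference_id`
#'   attribute.
#' @examples
#' aln <- c(ref = "MA-RK", other = "MAQRK")
#' map_reference_residues(aln, key_residue_spec("ref", 3, "R"))
#' @export
map_reference_residues <- function(alignment, spec,
                                   reference_id = attr(spec, "reference_id")) {
  alignment <- as_alignment(alignment)
  if (!reference_id %in% names(alignment)) {
    cld_abort(paste0("Reference sequence '", reference_id,
                     "' is absent from the alignment."),
              "missing_reference")
  }
  ref_chars <- strsplit(toupper(alignment[[reference_id]]), "")[[1]]
  occupied <- which(!is_gap(ref_chars))
  if (any(spec$position > length(occupied))) {
    bad <- spec$position[spec$position > length(occupied)][1]
    cld_abort(paste0("Spec position ", bad, " exceeds the ungapped reference ",
                     "length (", length(occupied), ")."),
              "range_error")
  }
  columns <- occupied[spec$position]
  found <- ref_chars[columns]
  if (any(found != spec$aa)) {
    i <- which(found != spec$aa)[1]
    cld_abort(paste0("Reference has '", found[i], "' at position ",
                     spec$position[i], " but the spec expects '",
                     spec$aa[i], "'."),
              "spec_mismatch")
  }
  out <- tibble(position = spec$position, aa = spec$aa,
                column = as.integer(columns))
  attr(out, "reference_id") <- reference_id
  class(out) <- c("residue_map", class(out))
  out
}

#' Count intact key residues per protein
#'
#' For each protein, counts the mapped alignment columns at which its
#' character equals the expected amino acid (case-insensitive exact match;
#' gaps and ambiguity codes never match). Columns where the protein carries
#' a gap are reported separately so truncated metagenomic fragments can be
#' distinguished from substitutions downstream.
#'
#' @param alignment Named character vector (or AAStringSet) of aligned
#'   sequences.
#' @param residue_map Output of [map_reference_residues()].
#' @param ids Protein ids to score; defaults to every sequence.
#' @return Tibble with columns `protein_id`, `n_key_residues` (0 to the
#'   number of mapped residues), `n_key_gaps`.
#' @export
count_key_residues <- function(alignment, residue_map, ids = NULL) {
  alignment <- as_alignment(alignment)
  if (is.null(ids)) ids <- names(alignment)
  absent <- setdiff(ids, names(alignment))
  if (length(absent) > 0) {
    cld_abort(paste0("Sequence(s) absent from alignment: ",
                     paste(absent, collapse = ", ")),
              "missing_sequence")
  }
  m <- aln_matrix(alignment, ids)
  chars <- m[, residue_map$column, drop = FALSE]
  hits <- sweep(chars, 2, residue_map$aa, "==")
  tibble(
    protein_id = ids,
    n_key_residues = as.integer(rowSums(hits)),
    n_key_gaps = as.integer(rowSums(matrix(is_gap(chars), nrow = length(ids))))
  )
}

#' Classify a protein as Cld from its key-residue count
#'
#' A protein from the family alignment is called Cld if and only if all four
#' catalytic key residues are intact. Family membership is a property of the
#' input alignment and is not re-checked here.
#'
#' @param count Integer vector of key-residue counts (0-4).
#' @param n_required Number of residues required for a Cld call (default 4).
#' @return Logical vector, `TRUE` where `count == n_required`.
#' @export
classify_cld <- function(count, n_required = 4L) {
  if (any(count < 0 | count > n_required)) {
    cld_abort(paste0("Key-residue counts must lie in 0..", n_required, "."),
              "parameter_error")
  }
  count == n_required
}

#' N- and C-terminal extensions relative to the average Cld span
#'
#' Computes the mean first-occupied and mean last-occupied alignment column
#' over the supplied Cld proteins (arithmetic mean, rounded half away from
#' zero), then for each protein counts its residues in columns strictly
#' before the mean start (N-terminal extension) and strictly after the mean
#' end (C-terminal extension). Extensions longer than `long_threshold`
#' residues on either side are flagged: such proteins may be artifacts of
#' gene prediction or genuine fusion proteins.
#'
#' @param alignment Named character vector (or AAStringSet) of aligned
#'   sequences.
#' @param cld_ids Ids of Cld proteins over which the mean span is computed
#'   and extensions are reported.
#' @param long_threshold Residue count above which an extension is flagged
#'   (default 20).
#' @return Tibble with columns `protein_id`, `n_term_extension`,
#'   `c_term_extension`, `long_extension_flag`, plus attributes
#'   `mean_start_column` and `mean_end_column`.
#' @export
terminal_extensions <- function(alignment, cld_ids, long_threshold = 20) {
  alignment <- as_alignment(alignment)
  if (length(cld_ids) == 0) {
    cld_abort("`cld_ids` must be non-empty.", "empty_input")
  }
  absent <- setdiff(cld_ids, names(alignment))
  if (length(absent) > 0) {
    cld_abort(paste0("Sequence(s) absent from alignment: ",
                     paste(absent, collapse = ", ")),
              "missing_sequence")
  }
  m <- aln_matrix(alignment, cld_ids)
  occ <- matrix(!is_gap(m), nrow = nrow(m))
  first_col <- apply(occ, 1, function(r) which(r)[1])
  last_col <- apply(occ, 1, function(r) max(which(r)))
  if (any(is.na(first_col))) {
    cld_abort("A sequence consists entirely of gaps.", "format_error")
  }
  mean_start <- as.integer(round_half_away(mean(first_col)))
  mean_end <- as.integer(round_half_away(mean(last_col)))
  n_ext <- vapply(seq_along(cld_ids), function(i) {
    sum(occ[i, seq_len(mean_start - 1)])
  }, integer(1))
  width <- ncol(m)
  c_ext <- vapply(seq_along(cld_ids), function(i) {
    if (mean_end >= width) 0L else sum(occ[i, (mean_end + 1):width])
  }, integer(1))
  out <- tibble(
    protein_id = cld_ids,
    n_term_extension = n_ext,
    c_term_extension = c_ext,
    long_extension_flag = n_ext > long_threshold | c_ext > long_threshold
  )
  attr(out, "mean_start_column") <- mean_start
  attr(out, "mean_end_column") <- mean_end
  out
}

#' Identify Cld proteins in a family alignment
#'
#' End-to-end Cld caller: maps the catalytic key residues from the reference
#' onto alignment columns, counts intact residues for every protein,
#' classifies Cld (all residues intact), measures terminal extensions of the
#' called Cld relative to their average span, and merges optional external
#' signal-peptide predictions.
#'
#' @param alignment Named character vector, AAStringSet, or path to an
#'   aligned FASTA file.
#' @param reference_id Identifier of the reference sequence.
#' @param spec Key-residue specification; defaults to the canonical four
#'   residues ([default_key_residues()]).
#' @param signal_peptides Optional data frame with columns `protein_id` and
#'   `signal_peptide` (logical), e.g. parsed from an external predictor's
#'   output. Never computed here.
#' @param long_threshold Extension length above which `long_extension_flag`
#'   is set (default 20 residues).
#' @return A tibble of Cld calls: `protein_id`, `n_key_residues`,
#'   `n_key_gaps`, `is_cld`, `n_term_extension`, `c_term_extension`,
#'   `long_extension_flag`, `signal_peptide` (NA where unknown). Extension
#'   columns are NA for non-Cld proteins.
#' @export
cld_calls <- function(alignment, reference_id,
                      spec = default_key_residues(reference_id),
                      signal_peptides = NULL, long_threshold = 20) {
  if (is.character(alignment) && is.null(names(alignment)) &&
      length(alignment) == 1 && file.exists(alignment)) {
    alignment <- read_alignment(alignment)
  }
  alignment <- as_alignment(alignment)
  rmap <- map_reference_residues(alignment, spec, reference_id)
  counts <- count_key_residues(alignment, rmap)
  calls <- counts %>%
    dplyr::mutate(is_cld = classify_cld(.data$n_key_residues, nrow(rmap)))
  cld_ids <- calls$protein_id[calls$is_cld]
  if (length(cld_ids) > 0) {
    ext <- terminal_extensions(alignment, cld_ids, long_threshold)
    calls <- dplyr::left_join(calls, ext, by = "protein_id")
  } else {
    calls <- calls %>%
      dplyr::mutate(n_term_extension = NA_integer_,
                    c_term_extension = NA_integer_,
                    long_extension_flag = NA)
  }
  if (!is.null(signal_peptides)) {
    sp <- as_tibble(signal_peptides) %>%
      dplyr::select("protein_id", "signal_peptide")
    calls <- dplyr::left_join(calls, sp, by = "protein_id")
  } else {
    calls$signal_peptide <- NA
  }
  calls
}

#' Per-residue key-residue indicators
#'
#' Like [count_key_residues()] but reports one logical column per key
#' residue (named `res_<aa><position>`, e.g. `res_R127`), for per-clade
#' conservation summaries.
#'
#' @inheritParams count_key_residues
#' @return Tibble with `protein_id` and one logical column per mapped
#'   residue.
#' @export
key_residue_hits <- function(alignment, residue_map, ids = NULL) {
  alignment <- as_alignment(alignment)
  if (is.null(ids)) ids <- names(alignment)
  absent <- setdiff(ids, names(alignment))
  if (length(absent) > 0) {
    cld_abort(paste0("Sequence(s) absent from alignment: ",
                     paste(absent, collapse = ", ")),
              "missing_sequence")
  }
  m <- aln_matrix(alignment, ids)
  chars <- m[, residue_map$column, drop = FALSE]
  hits <- sweep(chars, 2, residue_map$aa, "==")
  colnames(hits) <- paste0("res_", residue_map$aa, residue_map$position)
  dplyr::bind_cols(tibble(protein_id = ids), as_tibble(hits))
}

#' Read signal-peptide predictions from a TSV
#'
#' Ingests per-protein signal-peptide calls produced by an external
#' predictor. Expected columns: `protein_id`, `signal_peptide`
#' (TRUE/FALSE).
#'
#' @param path Path to a tab-separated file with a header.
#' @return Tibble with columns `protein_id`, `signal_peptide`.
#' @export
read_signal_peptides <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    protein_id = readr::col_character(),
    signal_peptide = readr::col_logical()
  ))
}
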