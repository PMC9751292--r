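#' Import a subfamily clustering from representative-member TSV
#'
#' Reads the standard two-column cluster format (representative TAB member,
#' one pair per line, no header) produced by common sequence-clustering
#' tools, and returns a subfamily assignment keyed by representative.
#'
#' @param path Path to the two-column TSV.
#' @return A `subfamily_assignment` tibble with columns `protein_id`,
#'   `subfamily_id` (the representative id) and `representative`.
#' @export
import_cluster_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(new_subfamily_assignment(tibble(protein_id = character(),
                                           subfamily_id = character(),
                                           representative = character())))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad) > 0) {
    cld_abort(paste0("Malformed cluster line ", bad[1], " in '", path,
                     "': expected two tab-separated columns."),
              "parse_error")
  }
  rep_id <- vapply(parts, `[[`, character(1), 1)
  member <- vapply(parts, `[[`, character(1), 2)
  dup <- member[duplicated(member)]
  conflicting <- unique(dup[vapply(dup, function(m) {
    length(unique(rep_id[member == m])) > 1
  }, logical(1))])
  if (length(conflicting) > 0) {
    cld_abort(paste0("Member '", conflicting[1],
                     "' is listed under two representatives."),
              "consistency_error")
  }
  out <- tibble(protein_id = member, subfamily_id = rep_id,
                representative = rep_id) %>%
    dplyr::distinct()
  new_subfamily_assignment(out)
}

new_subfamily_assignment <- function(x) {
  class(x) <- c("subfamily_assignment", class(x))
  x
}

#' Subfamily sizes
#'
#' @param assignment A `subfamily_assignment`.
#' @return Tibble with `subfamily_id`, `representative`, `n_members`.
#' @export
subfamily_sizes <- function(assignment) {
  assignment %>%
    as_tibble() %>%
    dplyr::count(.data$subfamily_id, .data$representative,
                 name = "n_members")
}

kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(seq)
  unique(substring(seq, 1:(n - k + 1), k:n))
}

#' Greedy k-mer subfamily clustering
#'
#' A deterministic, alignment-free clusterer for neighborhood proteins,
#' used when no external clustering is supplied. Proteins are processed in
#' decreasing length order (ties broken by id). Each protein joins the
#' first existing subfamily with k-mer containment identity
#' `>= min_identity` and mutual length coverage `>= min_coverage` against
#' that subfamily, else it founds a new subfamily. Containment identity is
#' the number of the candidate's k-mers found in the subfamily's k-mer
#' profile (the union of its members' k-mers), divided by the smaller of
#' the candidate's and the representative's k-mer set sizes; coverage is
#' the shorter of the candidate's and representative's lengths divided by
#' the longer. The representative is the subfamily's founding (longest)
#' member. This approximates, but does not reproduce, alignment-based
#' clustering; externally imported clusterings ([import_cluster_tsv()])
#' are authoritative.
#'
#' @param proteins Named character vector of protein sequences (ungapped),
#'   or an AAStringSet.
#' @param min_identity Minimum k-mer containment identity (default 0.5).
#' @param min_coverage Minimum mutual length coverage (default 0.5).
#' @param kmer K-mer length (default 5).
#' @return A `subfamily_assignment` tibble (`protein_id`, `subfamily_id`,
#'   `representative`); subfamily ids are the representative protein ids.
#' @export
greedy_cluster <- function(proteins, min_identity = 0.5, min_coverage = 0.5,
                           kmer = 5L) {
  if (inherits(proteins, "XStringSet")) {
    proteins <- stats::setNames(as.character(proteins), names(proteins))
  }
  if (length(proteins) == 0) {
    return(new_subfamily_assignment(tibble(protein_id = character(),
                                           subfamily_id = character(),
                                           representative = character())))
  }
  if (any(!nzchar(proteins))) {
    cld_abort(paste0("Empty sequence: ",
                     names(proteins)[!nzchar(proteins)][1]),
              "input_error")
  }
  proteins <- toupper(proteins)
  ord <- order(-nchar(proteins), names(proteins))
  proteins <- proteins[ord]
  ids <- names(proteins)
  lens <- nchar(proteins)

  rep_ids <- character(0)
  rep_nkmer <- integer(0)     # k-mer set size of the founding member
  profile <- list()           # union of member k-mers per subfamily
  rep_lens <- integer(0)
  assignment <- character(length(proteins))
  for (i in seq_along(proteins)) {
    km <- kmer_set(proteins[[i]], kmer)
    joined <- NA_integer_
    for (j in seq_along(rep_ids)) {
      cov <- min(lens[i], rep_lens[j]) / max(lens[i], rep_lens[j])
      if (cov < min_coverage) next
      shared <- sum(km %in% profile[[j]])
      ident <- shared / min(length(km), rep_nkmer[j])
      if (ident >= min_identity) {
        joined <- j
        break
      }
    }
    if (is.na(joined)) {
      rep_ids <- c(rep_ids, ids[i])
      profile[[length(rep_ids)]] <- km
      rep_nkmer <- c(rep_nkmer, length(km))
      rep_lens <- c(rep_lens, lens[i])
      assignment[i] <- ids[i]
    } else {
      assignment[i] <- rep_ids[joined]
      profile[[joined]] <- unique(c(profile[[joined]], km))
    }
  }
  new_subfamily_assignment(tibble(protein_id = ids,
                                  subfamily_id = assignment,
                                  representative = assignment))
}

#' Force Cld lineages into fixed subfamily ids
#'
#' Relabels the subfamilies of identified Cld proteins to the fixed ids
#' `cld_1` and `cld_2` so the two Cld lineages appear as distinct, stably
#' named rows in linkage tables regardless of how the clusterer grouped
#' them.
#'
#' @param assignment A `subfamily_assignment`.
#' @param cld_lineages Data frame with columns `protein_id` and `lineage`
#'   (1 or 2).
#' @return The assignment with Cld proteins relabelled.
#' @export
force_cld_subfamilies <- function(assignment, cld_lineages) {
  cld_lineages <- as_tibble(cld_lineages)
  if (!all(cld_lineages$lineage %in% c(1, 2))) {
    cld_abort("`lineage` must be 1 or 2.", "parameter_error")
  }
  relabel <- stats::setNames(paste0("cld_", cld_lineages$lineage),
                             cld_lineages$protein_id)
  hit <- assignment$protein_id %in% names(relabel)
  assignment$subfamily_id[hit] <- relabel[assignment$protein_id[hit]]
  assignment$representative[hit] <- assignment$subfamily_id[hit]
  assignment
}

#' Write a subfamily assignment as representative-member TSV
#'
#' @param assignment A `subfamily_assignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_tsv <- function(assignment, path) {
  writeLines(paste(assignment$subfamily_id, assignment$protein_id,
                   sep = "\t"), path)
  invisible(path)
}
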