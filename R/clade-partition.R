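#' Partition a rooted tree into clades by mean node-to-leaf distance
#'
#' Traverses the tree in pre-order from the root. At each node the mean of
#' the path lengths from that node to all of its descendant leaves is
#' computed; the first (shallowest) node on each root-to-leaf path whose
#' mean distance is within the threshold is emitted as a clade, and its
#' subtree is not descended further. Leaves reached without any qualifying
#' ancestor become singleton clades. The result is a disjoint cover of the
#' leaf set in which every clade satisfies the distance bound and no clade's
#' parent does (maximality).
#'
#' @param tree A rooted `phylo` object with branch lengths (Newick files can
#'   be read with [ape::read.tree()]). Multifurcations and zero-length
#'   branches are allowed.
#' @param threshold Non-negative distance threshold, in branch-length units.
#' @param inclusive If `TRUE` (default) a node qualifies when its mean
#'   distance is `<=` the threshold; if `FALSE`, strictly `<`. The two
#'   differ only at exact equality.
#' @return A `cld_clade_partition`: a tibble with one row per leaf, columns
#'   `clade_id` (assigned by pre-order discovery rank: "clade_1", ...),
#'   `node` (ape node number of the clade root), `mean_distance`, and
#'   `protein_id` (the leaf label). The threshold is kept as an attribute.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:3,D:3):1);")
#' partition_clades(tr, threshold = 2)
#' @export
partition_clades <- function(tree, threshold, inclusive = TRUE) {
  if (!inherits(tree, "phylo")) {
    cld_abort("`tree` must be a `phylo` object.", "format_error")
  }
  if (is.null(tree$edge.length)) {
    cld_abort("Tree has no branch lengths.", "format_error")
  }
  if (!ape::is.rooted(tree)) {
    cld_abort("Tree must be rooted.", "format_error")
  }
  if (any(tree$edge.length < 0)) {
    cld_abort("Branch lengths must be non-negative.", "format_error")
  }
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0) {
    cld_abort("`threshold` must be a single non-negative number.",
              "parameter_error")
  }
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L

  # Postorder accumulation of (sum of distances to descendant leaves,
  # number of descendant leaves) for every node; leaves contribute (0, 1).
  sum_d <- numeric(n_node)
  n_leaf <- integer(n_node)
  n_leaf[seq_len(n_tip)] <- 1L
  po <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    parent <- po$edge[i, 1]
    child <- po$edge[i, 2]
    len <- po$edge.length[i]
    sum_d[parent] <- sum_d[parent] + sum_d[child] + n_leaf[child] * len
    n_leaf[parent] <- n_leaf[parent] + n_leaf[child]
  }
  mean_d <- sum_d / n_leaf

  qualifies <- if (inclusive) mean_d <= threshold else mean_d < threshold

  children <- split(tree$edge[, 2], tree$edge[, 1])

  # Pre-order: emit the shallowest qualifying node on each path; leaves that
  # never meet a qualifying ancestor qualify themselves (mean distance 0,
  # unless inclusive = FALSE and threshold = 0, where they are still emitted
  # as singletons because the partition must cover the leaf set).
  clade_nodes <- integer(0)
  stack <- root
  while (length(stack) > 0) {
    node <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (qualifies[node] || node <= n_tip) {
      clade_nodes <- c(clade_nodes, node)
    } else {
      kids <- children[[as.character(node)]]
      # push in reverse so the leftmost child is visited first
      stack <- c(stack, rev(kids))
    }
  }

  leaf_rows <- purrr::map2_dfr(
    clade_nodes, seq_along(clade_nodes),
    function(node, rank) {
      tips <- descendant_tips(tree, node, n_tip, children)
      tibble(clade_id = paste0("clade_", rank),
             node = node,
             mean_distance = mean_d[node],
             protein_id = tree$tip.label[tips])
    })
  attr(leaf_rows, "threshold") <- threshold
  attr(leaf_rows, "inclusive") <- inclusive
  class(leaf_rows) <- c("cld_clade_partition", class(leaf_rows))
  leaf_rows
}

descendant_tips <- function(tree, node, n_tip, children) {
  if (node <= n_tip) return(node)
  tips <- integer(0)
  stack <- node
  while (length(stack) > 0) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (cur <= n_tip) {
      tips <- c(tips, cur)
    } else {
      stack <- c(stack, rev(children[[as.character(cur)]]))
    }
  }
  tips
}

#' Summarise annotations per clade
#'
#' Joins per-protein annotations onto a clade partition and reports, for
#' each clade: protein counts by source, the fraction of proteins with each
#' key residue intact (any logical annotation column prefixed `res_`), the
#' fraction with a signal peptide, ungapped length statistics, the number of
#' distinct genera, and whether the clade carries an identical protein
#' sequence in two different genera - the strongest signal of recent
#' horizontal gene transfer.
#'
#' @param partition A [partition_clades()] result.
#' @param annotations Data frame with one row per leaf: `protein_id`,
#'   optional `genus`, `source` ("genomic"/"metagenomic"), `sequence`
#'   (ungapped) or `length`, `signal_peptide`, and any `res_*` logical
#'   columns (see [key_residue_hits()]).
#' @return A tibble with one row per clade.
#' @export
summarize_clades <- function(partition, annotations) {
  annotations <- as_tibble(annotations)
  missing <- setdiff(partition$protein_id, annotations$protein_id)
  if (length(missing) > 0) {
    cld_abort(paste0("Missing annotation for leaf/leaves: ",
                     paste(utils::head(missing, 5), collapse = ", ")),
              "lookup_error")
  }
  dat <- dplyr::left_join(as_tibble(partition), annotations,
                          by = "protein_id")
  if (!"length" %in% names(dat) && "sequence" %in% names(dat)) {
    dat$length <- nchar(gsub("[-.]", "", dat$sequence))
  }
  res_cols <- grep("^res_", names(dat), value = TRUE)

  dat %>%
    dplyr::group_by(.data$clade_id) %>%
    dplyr::summarise(
      n_proteins = dplyr::n(),
      n_genomic = if ("source" %in% names(dat))
        sum(.data$source == "genomic") else NA_integer_,
      n_metagenomic = if ("source" %in% names(dat))
        sum(.data$source == "metagenomic") else NA_integer_,
      dplyr::across(dplyr::all_of(res_cols), ~ mean(.x),
                    .names = "frac_{.col}"),
      frac_signal_peptide = if ("signal_peptide" %in% names(dat))
        mean(.data$signal_peptide, na.rm = TRUE) else NA_real_,
      length_min = if ("length" %in% names(dat))
        min(.data$length) else NA_real_,
      length_q1 = if ("length" %in% names(dat))
        stats::quantile(.data$length, 0.25, names = FALSE) else NA_real_,
      length_mean = if ("length" %in% names(dat))
        mean(.data$length) else NA_real_,
      length_q3 = if ("length" %in% names(dat))
        stats::quantile(.data$length, 0.75, names = FALSE) else NA_real_,
      length_max = if ("length" %in% names(dat))
        max(.data$length) else NA_real_,
      n_genera = if ("genus" %in% names(dat))
        dplyr::n_distinct(.data$genus) else NA_integer_,
      cross_genus_identical = if (all(c("genus", "sequence") %in% names(dat)))
        has_cross_genus_identical(.data$sequence, .data$genus) else NA,
      .groups = "drop"
    ) %>%
    dplyr::arrange(as.integer(sub("clade_", "", .data$clade_id)))
}

# TRUE iff some identical sequence occurs under >= 2 distinct genus labels.
has_cross_genus_identical <- function(sequence, genus) {
  any(tapply(genus, sequence, function(g) length(unique(g)) > 1))
}
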