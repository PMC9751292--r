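#' Build the subfamily co-occurrence network
#'
#' Represents each protein subfamily found in at least one *cld* genomic
#' neighborhood as a node, with an (unweighted, undirected) edge between
#' two distinct subfamilies whenever they occur together in at least
#' `min_count` neighborhoods. Multiple co-occurrences collapse to a single
#' edge; a subfamily occurring twice in one neighborhood creates no
#' self-loop.
#'
#' @param neighborhoods Neighborhood member table from
#'   [extract_neighborhoods()] (columns `neighborhood_id`, `protein_id`).
#' @param assignment A `subfamily_assignment` covering every member
#'   protein.
#' @param min_count Minimum number of neighborhoods in which a pair must
#'   co-occur to draw an edge (default 1).
#' @return A `cld_network` object: list with `nodes` (tibble
#'   `subfamily_id`, `n_neighborhoods`) and `edges` (tibble `from`, `to`
#'   with `from < to`, `n_cooccurrences`).
#' @export
build_network <- function(neighborhoods, assignment, min_count = 1L) {
  neighborhoods <- as_tibble(neighborhoods)
  lookup <- stats::setNames(assignment$subfamily_id, assignment$protein_id)
  unassigned <- setdiff(unique(neighborhoods$protein_id), names(lookup))
  if (length(unassigned) > 0) {
    cld_abort(paste0("Protein(s) without a subfamily assignment: ",
                     paste(utils::head(unassigned, 5), collapse = ", ")),
              "lookup_error")
  }
  neighborhoods$subfamily_id <- unname(lookup[neighborhoods$protein_id])

  per_nbh <- neighborhoods %>%
    dplyr::distinct(.data$neighborhood_id, .data$subfamily_id)

  nodes <- per_nbh %>%
    dplyr::count(.data$subfamily_id, name = "n_neighborhoods") %>%
    dplyr::arrange(.data$subfamily_id)

  pair_list <- split(per_nbh$subfamily_id, per_nbh$neighborhood_id)
  edges <- purrr::map_dfr(pair_list, function(sids) {
    sids <- sort(unique(sids))
    if (length(sids) < 2) {
      return(tibble(from = character(), to = character()))
    }
    idx <- utils::combn(length(sids), 2)
    tibble(from = sids[idx[1, ]], to = sids[idx[2, ]])
  })
  if (!"from" %in% names(edges)) {
    edges <- tibble(from = character(), to = character())
  }
  edges <- edges %>%
    dplyr::count(.data$from, .data$to, name = "n_cooccurrences") %>%
    dplyr::filter(.data$n_cooccurrences >= min_count) %>%
    dplyr::arrange(.data$from, .data$to)

  structure(list(nodes = nodes, edges = edges), class = "cld_network")
}

#' @export
print.cld_network <- function(x, ...) {
  cat("Subfamily co-occurrence network:", nrow(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

adjacency_list <- function(network) {
  nodes <- network$nodes$subfamily_id
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (n in nodes) adj[[n]] <- character(0)
  if (nrow(network$edges) > 0) {
    for (i in seq_len(nrow(network$edges))) {
      a <- network$edges$from[i]
      b <- network$edges$to[i]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  adj
}

#' Clustering coefficient of network nodes
#'
#' For a node with `k` neighbors and `e` edges among those neighbors,
#' the (local) clustering coefficient is `e / (k * (k - 1) / 2)`; it is 0
#' by convention when `k < 2`. Computed from integer edge counts, so the
#' value is exact up to the final division. A low coefficient marks a
#' subfamily whose neighbors are rarely connected to each other, i.e. a
#' gene recurring across many different types of genomic neighborhoods -
#' the signature of genetic linkage to the anchor gene.
#'
#' @param network A `cld_network` from [build_network()].
#' @param nodes Subfamily ids to score; defaults to all nodes.
#' @return Named numeric vector of coefficients in `[0, 1]`.
#' @export
clustering_coefficient <- function(network, nodes = NULL) {
  adj <- adjacency_list(network)
  if (is.null(nodes)) nodes <- network$nodes$subfamily_id
  unknown <- setdiff(nodes, names(adj))
  if (length(unknown) > 0) {
    cld_abort(paste0("Unknown node(s): ",
                     paste(utils::head(unknown, 5), collapse = ", ")),
              "lookup_error")
  }
  vapply(nodes, function(n) {
    nb <- adj[[n]]
    k <- length(nb)
    if (k < 2) return(0)
    # each edge among neighbors is counted twice in this sum
    e2 <- sum(vapply(nb, function(u) sum(adj[[u]] %in% nb), numeric(1)))
    (e2 / 2) / (k * (k - 1) / 2)
  }, numeric(1))
}

#' Rank subfamily linkage to the anchor gene
#'
#' Computes the clustering coefficient for every subfamily node and returns
#' a table sorted ascending by coefficient (ties broken by subfamily id).
#' Subfamilies with a coefficient strictly below `hit_threshold` are
#' flagged as linkage hits. For the anchor's own subfamilies (`cld_1`,
#' `cld_2`) the coefficient measures the diversity of genomic contexts the
#' anchor occurs in rather than linkage.
#'
#' @param network A `cld_network`.
#' @param hit_threshold Coefficient below which a subfamily is a hit
#'   (default 0.1; must lie in `[0, 1]`).
#' @param annotations Optional data frame of pass-through subfamily
#'   metadata (must have `subfamily_id`; e.g. product, function, mean
#'   length) joined onto the table.
#' @return A `cld_linkage` tibble: `subfamily_id`, `clustering_coefficient`,
#'   `n_neighborhoods`, `hit`, plus any annotation columns. The threshold is
#'   kept as an attribute.
#' @export
rank_linkage <- function(network, hit_threshold = 0.1, annotations = NULL) {
  if (!is.numeric(hit_threshold) || length(hit_threshold) != 1 ||
      hit_threshold < 0 || hit_threshold > 1) {
    cld_abort("`hit_threshold` must be a single number in [0, 1].",
              "parameter_error")
  }
  cc <- clustering_coefficient(network)
  out <- tibble(
    subfamily_id = network$nodes$subfamily_id,
    clustering_coefficient = unname(cc[network$nodes$subfamily_id]),
    n_neighborhoods = network$nodes$n_neighborhoods
  ) %>%
    dplyr::mutate(hit = .data$clustering_coefficient < hit_threshold) %>%
    dplyr::arrange(.data$clustering_coefficient, .data$subfamily_id)
  if (!is.null(annotations)) {
    out <- dplyr::left_join(out, as_tibble(annotations), by = "subfamily_id")
  }
  attr(out, "hit_threshold") <- hit_threshold
  class(out) <- c("cld_linkage", class(out))
  out
}

#' Export the network as an edge-list TSV
#'
#' @param network A `cld_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  readr::write_tsv(network$edges, path)
  invisible(path)
}

#' Convert the co-occurrence network to an igraph graph
#'
#' @param network A `cld_network`.
#' @return An igraph (undirected) graph; requires the igraph package.
#' @export
as_igraph <- function(network) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    cld_abort("The igraph package is required for this conversion.",
              "dependency_error")
  }
  igraph::graph_from_data_frame(
    network$edges[, c("from", "to")],
    directed = FALSE,
    vertices = network$nodes$subfamily_id
  )
}
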