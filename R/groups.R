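#' Subfamily presence/absence matrix over neighborhoods
#'
#' Builds the binary feature matrix for neighborhood grouping: one row per
#' genomic neighborhood with at least `min_genes` member genes, one column
#' per subfamily, entry 1 when the subfamily occurs in the neighborhood
#' (any number of times) and 0 otherwise.
#'
#' @param neighborhoods Neighborhood member table from
#'   [extract_neighborhoods()].
#' @param assignment A `subfamily_assignment` covering every member
#'   protein.
#' @param min_genes Minimum number of genes for a neighborhood to be
#'   included (default 10).
#' @return Integer 0/1 matrix with neighborhood ids as row names and
#'   subfamily ids as column names.
#' @export
presence_matrix <- function(neighborhoods, assignment, min_genes = 10L) {
  neighborhoods <- as_tibble(neighborhoods)
  lookup <- stats::setNames(assignment$subfamily_id, assignment$protein_id)
  unassigned <- setdiff(unique(neighborhoods$protein_id), names(lookup))
  if (length(unassigned) > 0) {
    cld_abort(paste0("Protein(s) without a subfamily assignment: ",
                     paste(utils::head(unassigned, 5), collapse = ", ")),
              "lookup_error")
  }
  sizes <- neighborhoods %>% dplyr::count(.data$neighborhood_id)
  keep <- sizes$neighborhood_id[sizes$n >= min_genes]
  nb <- neighborhoods %>%
    dplyr::filter(.data$neighborhood_id %in% keep) %>%
    dplyr::mutate(subfamily_id = unname(lookup[.data$protein_id])) %>%
    dplyr::distinct(.data$neighborhood_id, .data$subfamily_id)
  rows <- sort(unique(nb$neighborhood_id))
  cols <- sort(unique(nb$subfamily_id))
  m <- matrix(0L, nrow = length(rows), ncol = length(cols),
              dimnames = list(rows, cols))
  if (nrow(nb) > 0) {
    m[cbind(match(nb$neighborhood_id, rows),
            match(nb$subfamily_id, cols))] <- 1L
  }
  m
}

# Classic DBSCAN on a set of 2-d points. Returns integer labels where 0 is
# noise and clusters are numbered 1, 2, ... in order of discovery.
dbscan_labels <- function(coords, eps, min_samples) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  neighbors <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(neighbors, length, integer(1)) >= min_samples
  labels <- rep(0L, n)
  visited <- rep(FALSE, n)
  cluster <- 0L
  for (i in seq_len(n)) {
    if (visited[i] || !core[i]) next
    cluster <- cluster + 1L
    queue <- i
    visited[i] <- TRUE
    labels[i] <- cluster
    while (length(queue) > 0) {
      p <- queue[1]
      queue <- queue[-1]
      if (core[p]) {
        for (q in neighbors[[p]]) {
          if (labels[q] == 0L) labels[q] <- cluster
          if (!visited[q]) {
            visited[q] <- TRUE
            if (core[q]) queue <- c(queue, q)
          }
        }
      }
    }
  }
  labels
}

#' Group neighborhoods by subfamily content
#'
#' Reduces the presence/absence matrix with principal components analysis,
#' embeds the reduced coordinates into two dimensions with t-distributed
#' stochastic neighbor embedding (t-SNE), and groups neighborhoods lying
#' within `distance` units of each other in the embedding using
#' density-based clustering (DBSCAN). Neighborhoods not assigned to any
#' dense group are reported as the noise pseudo-group (group 0), mirroring
#' the catch-all group of unclustered neighborhoods.
#'
#' The embedding is stochastic: group labels are reproducible only for a
#' fixed seed, and label identities carry no meaning across seeds
#' (compare groupings with the adjusted Rand index, never raw labels).
#'
#' @param matrix Binary matrix from [presence_matrix()].
#' @param seed Integer seed controlling the embedding.
#' @param reduce_dims Number of principal components to keep before the
#'   embedding (default 50; clipped to the matrix dimensions).
#' @param perplexity t-SNE perplexity (default 50). The matrix must have
#'   more than `3 * perplexity` rows for the embedding to be well posed.
#' @param iterations t-SNE iterations (default 5000).
#' @param distance DBSCAN radius in embedding units (default 4).
#' @param min_samples DBSCAN core-point minimum (default 5).
#' @param theta Barnes-Hut accuracy/speed trade-off passed to the t-SNE
#'   backend; 0 computes the exact embedding (default 0).
#' @return A `cld_grouping` tibble: `neighborhood_id`, `group` (integer, 0
#'   = noise), `x`, `y` (embedding coordinates), with the full parameter
#'   record as a `parameters` attribute.
#' @export
embed_and_group <- function(matrix, seed, reduce_dims = 50L,
                            perplexity = 50, iterations = 5000L,
                            distance = 4, min_samples = 5L, theta = 0) {
  if (is.null(dim(matrix)) || nrow(matrix) == 0) {
    cld_abort("`matrix` must be a non-empty presence/absence matrix.",
              "parameter_error")
  }
  min_rows <- floor(3 * perplexity) + 2
  if (nrow(matrix) < min_rows) {
    cld_abort(paste0("Too few neighborhoods (", nrow(matrix),
                     ") for perplexity ", perplexity, "; at least ",
                     min_rows, " rows are required."),
              "wellposedness_error")
  }
  dims <- min(reduce_dims, ncol(matrix), nrow(matrix) - 1L)
  pca <- stats::prcomp(matrix, center = TRUE, scale. = FALSE)
  dims <- min(dims, ncol(pca$x))
  scores <- pca$x[, seq_len(dims), drop = FALSE]
  withr::with_seed(as.integer(seed), {
    emb <- Rtsne::Rtsne(scores, dims = 2, perplexity = perplexity,
                        max_iter = as.integer(iterations), theta = theta,
                        pca = FALSE, check_duplicates = FALSE,
                        verbose = FALSE)
  })
  coords <- emb$Y
  labels <- dbscan_labels(coords, eps = distance, min_samples = min_samples)
  out <- tibble(
    neighborhood_id = rownames(matrix),
    group = labels,
    x = coords[, 1],
    y = coords[, 2]
  )
  attr(out, "parameters") <- list(
    seed = as.integer(seed), reduce_dims = dims, perplexity = perplexity,
    iterations = as.integer(iterations), distance = distance,
    min_samples = as.integer(min_samples), theta = theta
  )
  class(out) <- c("cld_grouping", class(out))
  out
}

#' Write a presence matrix as sparse coordinate TSV
#'
#' @param matrix Matrix from [presence_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_presence_matrix <- function(matrix, path) {
  idx <- which(matrix != 0, arr.ind = TRUE)
  out <- tibble(
    neighborhood_id = rownames(matrix)[idx[, 1]],
    subfamily_id = colnames(matrix)[idx[, 2]]
  ) %>% dplyr::arrange(.data$neighborhood_id, .data$subfamily_id)
  readr::write_tsv(out, path)
  invisible(path)
}
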