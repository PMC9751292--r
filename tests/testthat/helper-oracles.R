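# Independent oracles and fixture builders shared across tests.

# Random undirected simple graph as a cld_network object.
random_network <- function(n_nodes, p_edge) {
  ids <- sprintf("s%02d", seq_len(n_nodes))
  pairs <- t(utils::combn(n_nodes, 2))
  keep <- stats::runif(nrow(pairs)) < p_edge
  edges <- tibble::tibble(from = ids[pairs[keep, 1]],
                          to = ids[pairs[keep, 2]],
                          n_cooccurrences = 1L)
  structure(list(nodes = tibble::tibble(subfamily_id = ids,
                                        n_neighborhoods = 1L),
                 edges = edges),
            class = "cld_network")
}

# Brute-force clustering coefficient: adjacency matrix + explicit loop over
# neighbor pairs (triangle enumeration). Independent of the package's
# adjacency-list implementation.
cc_oracle <- function(network) {
  ids <- network$nodes$subfamily_id
  n <- length(ids)
  adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  if (nrow(network$edges) > 0) {
    adj[cbind(network$edges$from, network$edges$to)] <- TRUE
    adj[cbind(network$edges$to, network$edges$from)] <- TRUE
  }
  out <- numeric(n)
  names(out) <- ids
  for (i in seq_len(n)) {
    nb <- which(adj[i, ])
    k <- length(nb)
    if (k < 2) next
    e <- 0L
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        if (adj[nb[a], nb[b]]) e <- e + 1L
      }
    }
    out[i] <- e / (k * (k - 1) / 2)
  }
  out
}

# Brute-force clade partition: mean node-to-leaf distances from
# ape::dist.nodes (an independent path computation), then greedy selection
# of the highest qualifying node on each root-to-leaf path.
clade_oracle <- function(tree, threshold) {
  n_tip <- length(tree$tip.label)
  d <- ape::dist.nodes(tree)
  n_node <- n_tip + tree$Nnode
  tips_under <- function(node) {
    if (node <= n_tip) return(node)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_under))
  }
  mean_dist <- vapply(seq_len(n_node), function(v) {
    mean(d[v, tips_under(v)])
  }, numeric(1))
  clades <- list()
  walk <- function(node) {
    if (mean_dist[node] <= threshold || node <= n_tip) {
      clades[[length(clades) + 1]] <<- sort(tree$tip.label[tips_under(node)])
    } else {
      kids <- tree$edge[tree$edge[, 1] == node, 2]
      for (k in kids) walk(k)
    }
  }
  walk(n_tip + 1L)
  clades
}

partition_leaf_sets <- function(partition) {
  unname(lapply(split(partition$protein_id, partition$clade_id), sort))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Assignment taken straight from generator truth (ground-truth subfamilies).
truth_assignment <- function(dataset) {
  gs <- dataset$truth$gene_subfamilies
  cldatlas:::new_subfamily_assignment(
    tibble::tibble(protein_id = gs$protein_id,
                   subfamily_id = gs$true_subfamily,
                   representative = gs$true_subfamily))
}

# Two-archetype study conditions: disjoint repertoires, optionally one
# shared associated subfamily planted next to every anchor.
archetype_config <- function(seed, n_per_archetype, shared = FALSE,
                             repertoire_size = 25, genes_per_contig = 25) {
  archetypes <- list(
    arch_A = sprintf("A%02d", seq_len(repertoire_size)),
    arch_B = sprintf("B%02d", seq_len(repertoire_size))
  )
  assoc <- if (shared)
    tibble::tibble(subfamily_id = "shared_link", prob = 1, offset_range = 3)
  else NULL
  synth_config(
    seed = seed,
    n_contigs = 2 * n_per_archetype,
    genes_per_contig = genes_per_contig,
    n_anchors = 2 * n_per_archetype,
    associated_subfamilies = assoc,
    background_subfamilies = 10,
    archetypes = archetypes
  )
}
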