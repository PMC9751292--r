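#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a co-occurrence network into its node table
#'
#' @param x A `cld_network`.
#' @param ... Unused.
#' @return Tibble with `subfamily_id`, `n_neighborhoods`, `degree`,
#'   `clustering_coefficient`.
#' @method tidy cld_network
#' @export
tidy.cld_network <- function(x, ...) {
  deg <- stats::setNames(rep(0L, nrow(x$nodes)), x$nodes$subfamily_id)
  if (nrow(x$edges) > 0) {
    tab <- table(c(x$edges$from, x$edges$to))
    deg[names(tab)] <- as.integer(tab)
  }
  cc <- clustering_coefficient(x)
  x$nodes %>%
    dplyr::mutate(degree = unname(deg[.data$subfamily_id]),
                  clustering_coefficient = unname(cc[.data$subfamily_id]))
}

#' @rdname tidy.cld_network
#' @method glance cld_network
#' @export
glance.cld_network <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         mean_clustering_coefficient =
           if (nrow(x$nodes) > 0) mean(clustering_coefficient(x))
           else NA_real_)
}

#' Tidy / summarise a linkage table
#'
#' @param x A `cld_linkage` from [rank_linkage()].
#' @param ... Unused.
#' @method tidy cld_linkage
#' @export
tidy.cld_linkage <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "cld_linkage")
  out
}

#' @rdname tidy.cld_linkage
#' @method glance cld_linkage
#' @export
glance.cld_linkage <- function(x, ...) {
  tibble(n_subfamilies = nrow(x), n_hits = sum(x$hit),
         hit_threshold = attr(x, "hit_threshold"),
         min_coefficient = if (nrow(x) > 0)
           min(x$clustering_coefficient) else NA_real_)
}

#' Tidy / summarise a clade partition
#'
#' @param x A `cld_clade_partition` from [partition_clades()].
#' @param ... Unused.
#' @return `tidy()`: one row per clade (`clade_id`, `node`,
#'   `mean_distance`, `n_proteins`); `glance()`: one-row summary.
#' @method tidy cld_clade_partition
#' @export
tidy.cld_clade_partition <- function(x, ...) {
  as_tibble(x) %>%
    dplyr::group_by(.data$clade_id, .data$node, .data$mean_distance) %>%
    dplyr::summarise(n_proteins = dplyr::n(), .groups = "drop") %>%
    dplyr::arrange(as.integer(sub("clade_", "", .data$clade_id)))
}

#' @rdname tidy.cld_clade_partition
#' @method glance cld_clade_partition
#' @export
glance.cld_clade_partition <- function(x, ...) {
  per <- tidy(x)
  tibble(n_clades = nrow(per), n_leaves = nrow(as_tibble(x)),
         threshold = attr(x, "threshold"),
         largest_clade = if (nrow(per) > 0) max(per$n_proteins)
           else NA_integer_)
}

#' Tidy / summarise a neighborhood grouping
#'
#' @param x A `cld_grouping` from [embed_and_group()].
#' @param ... Unused.
#' @method tidy cld_grouping
#' @export
tidy.cld_grouping <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "cld_grouping")
  out
}

#' @rdname tidy.cld_grouping
#' @method glance cld_grouping
#' @export
glance.cld_grouping <- function(x, ...) {
  tibble(n_neighborhoods = nrow(x),
         n_groups = length(setdiff(unique(x$group), 0L)),
         n_noise = sum(x$group == 0L))
}

#' Plot the distribution of clustering coefficients
#'
#' Histogram of per-subfamily clustering coefficients with the hit
#' threshold marked; subfamilies left of the line are linkage hits.
#'
#' @param object A `cld_linkage`.
#' @param bins Histogram bin count (default 50).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cld_linkage
#' @export
autoplot.cld_linkage <- function(object, bins = 50, ...) {
  thr <- attr(object, "hit_threshold")
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$clustering_coefficient)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "clustering coefficient (linkage to cld)",
                  y = "subfamilies",
                  title = "Subfamily linkage to cld",
                  subtitle = paste0("hits: coefficient < ", thr)) +
    ggplot2::theme_minimal()
}

#' Plot the neighborhood-group embedding
#'
#' @param object A `cld_grouping`.
#' @param ... Unused.
#' @return A ggplot of the two embedding dimensions coloured by group
#'   (noise in grey).
#' @method autoplot cld_grouping
#' @export
autoplot.cld_grouping <- function(object, ...) {
  dat <- as_tibble(object) %>%
    dplyr::mutate(group = factor(ifelse(.data$group == 0L, "noise",
                                        paste0("group ", .data$group))))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = .data$group)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::labs(x = "embedding 1", y = "embedding 2",
                  colour = "neighborhood group") +
    ggplot2::theme_minimal()
}

#' Plot clade sizes of a partition
#'
#' @param object A `cld_clade_partition`.
#' @param ... Unused.
#' @return A ggplot barplot of proteins per clade.
#' @method autoplot cld_clade_partition
#' @export
autoplot.cld_clade_partition <- function(object, ...) {
  per <- tidy(object)
  per$clade_id <- factor(per$clade_id, levels = per$clade_id)
  ggplot2::ggplot(per, ggplot2::aes(x = .data$clade_id,
                                    y = .data$n_proteins)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "proteins per clade") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
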