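nbh_fixture <- function(...) {
  sets <- list(...)
  purrr::imap_dfr(sets, function(subfams, i) {
    tibble::tibble(neighborhood_id = paste0("n", i),
                   protein_id = paste0("n", i, "_", seq_along(subfams)),
                   subfam = subfams)
  })
}

assignment_from_column <- function(nbh) {
  cldatlas:::new_subfamily_assignment(tibble::tibble(
    protein_id = nbh$protein_id,
    subfamily_id = nbh$subfam,
    representative = nbh$subfam))
}

test_that("co-occurrence edges are built per neighborhood without self-loops", {
  nbh <- nbh_fixture(c("A", "B", "C"))
  net <- build_network(nbh, assignment_from_column(nbh))
  expect_equal(nrow(net$nodes), 3)
  expect_equal(nrow(net$edges), 3) # triangle
  expect_true(all(net$edges$from != net$edges$to))

  nbh2 <- nbh_fixture(c("A", "B"), c("C", "D"))
  net2 <- build_network(nbh2, assignment_from_column(nbh2))
  expect_equal(nrow(net2$edges), 2)

  # a subfamily occurring twice in one neighborhood: node, no self-loop
  nbh3 <- nbh_fixture(c("A", "A", "B"))
  net3 <- build_network(nbh3, assignment_from_column(nbh3))
  expect_equal(nrow(net3$nodes), 2)
  expect_equal(nrow(net3$edges), 1)
  expect_equal(net3$nodes$n_neighborhoods, c(1L, 1L))

  missing <- nbh_fixture(c("A", "B"))
  asg <- assignment_from_column(missing)[-1, ]
  expect_error(build_network(missing, asg), "n1_1",
               class = "cldatlas_lookup_error")
})

test_that("duplicate co-occurrences collapse unless below min_count", {
  nbh <- nbh_fixture(c("A", "B"), c("A", "B"), c("A", "C"))
  net <- build_network(nbh, assignment_from_column(nbh))
  expect_equal(nrow(net$edges), 2)
  expect_equal(net$edges$n_cooccurrences[net$edges$to == "B"], 2L)
  net2 <- build_network(nbh, assignment_from_column(nbh), min_count = 2)
  expect_equal(nrow(net2$edges), 1)
})

test_that("clustering coefficient matches hand-computed cases", {
  nbh <- nbh_fixture(c("A", "B", "C"))
  net <- build_network(nbh, assignment_from_column(nbh))
  expect_equal(unname(clustering_coefficient(net, "A")), 1)

  # path A - B - C: the center has two unconnected neighbors
  nbh2 <- nbh_fixture(c("A", "B"), c("B", "C"))
  net2 <- build_network(nbh2, assignment_from_column(nbh2))
  cc2 <- clustering_coefficient(net2)
  expect_equal(unname(cc2["B"]), 0)
  expect_equal(unname(cc2["A"]), 0) # k = 1 convention

  # hub with 4 neighbors carrying 3 edges among them: 3/6
  nbh3 <- nbh_fixture(c("H", "A"), c("H", "B"), c("H", "C"), c("H", "D"),
                      c("A", "B"), c("B", "C"), c("C", "D"))
  net3 <- build_network(nbh3, assignment_from_column(nbh3))
  expect_equal(unname(clustering_coefficient(net3, "H")), 0.5)

  expect_error(clustering_coefficient(net3, "nope"),
               class = "cldatlas_lookup_error")
})

test_that("coefficients agree with igraph and are label-invariant", {
  withr::with_seed(42, {
    for (rep in 1:25) {
      net <- random_network(sample(4:20, 1), runif(1, 0.1, 0.7))
      cc <- clustering_coefficient(net)
      g <- as_igraph(net)
      ig <- igraph::transitivity(g, type = "local", isolates = "zero")
      names(ig) <- igraph::V(g)$name
      expect_equal(cc[names(ig)], ig, tolerance = 1e-12)

      # relabeling nodes permutes but does not change coefficients
      perm <- sample(nrow(net$nodes))
      relabel <- setNames(sprintf("z%02d", perm), net$nodes$subfamily_id)
      net2 <- net
      net2$nodes$subfamily_id <- unname(relabel[net$nodes$subfamily_id])
      net2$nodes <- net2$nodes[order(net2$nodes$subfamily_id), ]
      net2$edges$from2 <- unname(relabel[net2$edges$from])
      net2$edges$to2 <- unname(relabel[net2$edges$to])
      net2$edges <- tibble::tibble(
        from = pmin(net2$edges$from2, net2$edges$to2),
        to = pmax(net2$edges$from2, net2$edges$to2))
      cc2 <- clustering_coefficient(net2)
      expect_equal(unname(cc2[unname(relabel[names(cc)])]), unname(cc))
    }
  })
})

test_that("adding a clique neighborhood never lowers outside coefficients", {
  nbh <- nbh_fixture(c("A", "B"), c("B", "C"), c("C", "D"), c("A", "D"))
  net <- build_network(nbh, assignment_from_column(nbh))
  before <- clustering_coefficient(net)
  nbh2 <- dplyr::bind_rows(nbh,
                           nbh_fixture(c("E", "F", "G"))[, ] %>%
                             dplyr::mutate(neighborhood_id = "n99",
                                           protein_id = paste0("x", 1:3)))
  net2 <- build_network(nbh2, assignment_from_column(nbh2))
  after <- clustering_coefficient(net2)
  expect_true(all(after[names(before)] >= before - 1e-12))
})

test_that("linkage ranking sorts ascending and applies a strict hit rule", {
  # H has coefficient 0.5; spokes have 1 or 0 coefficients by construction
  nbh <- nbh_fixture(c("H", "A"), c("H", "B"), c("H", "C"), c("H", "D"),
                     c("A", "B"), c("B", "C"), c("C", "D"))
  net <- build_network(nbh, assignment_from_column(nbh))
  lt <- rank_linkage(net, hit_threshold = 0.5)
  expect_true(all(diff(lt$clustering_coefficient) >= 0))
  # coefficient exactly at the threshold is not a hit
  expect_false(lt$hit[lt$subfamily_id == "H"])
  expect_true(all(lt$hit[lt$clustering_coefficient < 0.5]))

  empty <- build_network(nbh_fixture(character(0)),
                         assignment_from_column(nbh_fixture("A")))
  expect_equal(nrow(rank_linkage(empty)), 0)

  expect_error(rank_linkage(net, hit_threshold = 1.5),
               class = "cldatlas_parameter_error")
})

test_that("annotations pass through the linkage table", {
  nbh <- nbh_fixture(c("A", "B", "C"))
  net <- build_network(nbh, assignment_from_column(nbh))
  ann <- tibble::tibble(subfamily_id = c("A", "B", "C"),
                        product = c("cupin", "SDR", "tRNA"))
  lt <- rank_linkage(net, annotations = ann)
  expect_equal(lt$product[lt$subfamily_id == "A"], "cupin")
  expect_equal(glance(lt)$n_subfamilies, 3)
})

test_that("shared subfamily across archetypes gets a low coefficient", {
  d <- generate_dataset(archetype_config(seed = 4, n_per_archetype = 60,
                                         shared = TRUE))
  nbh <- extract_neighborhoods(d$genes, d$truth$anchors$gene_id)
  net <- build_network(nbh, truth_assignment(d))
  cc <- clustering_coefficient(net)
  exclusive <- grep("^[AB]\\d+$", names(cc), value = TRUE)
  expect_lt(cc[["shared_link"]], median(cc[exclusive]))
})
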