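# Fixed Cld-like template (250 aa). The four catalytic key residues sit at
# their canonical ungapped positions: K92, H114, R127, E167. Using a fixed
# template keeps key-residue columns under exact control, which the
# residue-counting tests require.
CLD_TEMPLATE <- paste0(
  "RYLDCATMLNGDALREWEGCIHPVKFSVPDVPFGQTVYGHWQESKLPRWN",
  "FASGHFERCEGLWVCWWVSPSSFMPLLKTGPKNVIMISERNKPTYHMCPT",
  "GLWEDLGHERHAVHIEIVGQQCEGIKRGMQAKHDHPNFYNTPWDYSDPRV",
  "ETGRWKLARRDISQQYESNRYYKKKSFYLSCYNRPRTANPAMYFTTKPMM",
  "DRIERAANPAYWHLDNREQHVAWHNWDDIAICRKYCHTDVWCLQRSCNAH"
)
CLD_KEY_POSITIONS <- c(K = 92L, H = 114L, R = 127L, E = 167L)
CLD_REFERENCE_ID <- "Nwinogradskyi_ref"

GENUS_VOCAB <- c("Nitrobacter", "Nitrospira", "Pseudomonas", "Azospira",
                 "Dechloromonas", "Ideonella", "Nitrospina", "Sphingomonas")
PHYLUM_VOCAB <- c("Proteobacteria", "Nitrospirae", "Nitrospinae",
                  "Planctomycetes")

#' Configuration for the synthetic dataset generator
#'
#' Describes a synthetic comparative-genomics dataset with planted, known
#' structure: contigs of ordered genes, anchor *cld* genes, subfamilies
#' with controlled co-occurrence probabilities around the anchors, optional
#' neighborhood archetypes, controlled key-residue mutations, and an
#' optional cross-genus identical protein pair (a planted horizontal
#' gene transfer signal).
#'
#' @param seed Integer master seed; all randomness derives from it.
#' @param n_contigs Number of contigs (one genome per contig).
#' @param genes_per_contig Genes per contig.
#' @param n_anchors Number of planted *cld* anchor genes (at most
#'   `n_contigs * genes_per_contig`).
#' @param associated_subfamilies Data frame with columns `subfamily_id`,
#'   `prob` (co-occurrence probability in `[0, 1]`) and `offset_range`
#'   (the planted copy lands within that many positions of the anchor).
#'   May be `NULL`.
#' @param background_subfamilies Number of background subfamily templates
#'   genes are drawn from outside archetype windows.
#' @param archetypes Optional named list of character vectors: each element
#'   is a subfamily repertoire; anchors are assigned archetypes round-robin
#'   and their flanking genes are drawn from the repertoire.
#' @param residue_mutation_rate Probability that a planted cld protein
#'   loses one key residue (in `[0, 1]`).
#' @param cross_genus_identical If `TRUE`, one anchor protein sequence is
#'   duplicated verbatim under a second genus.
#' @param subfamily_mutation_rate Point-mutation rate applied to each
#'   subfamily member relative to its subfamily template (default 0.05).
#' @param radius Neighborhood half-width the archetype window uses
#'   (default 10).
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(seed = 1L, n_contigs = 10L, genes_per_contig = 50L,
                         n_anchors = 5L, associated_subfamilies = NULL,
                         background_subfamilies = 40L, archetypes = NULL,
                         residue_mutation_rate = 0,
                         cross_genus_identical = FALSE,
                         subfamily_mutation_rate = 0.05, radius = 10L) {
  cfg <- list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
              genes_per_contig = as.integer(genes_per_contig),
              n_anchors = as.integer(n_anchors),
              associated_subfamilies = if (is.null(associated_subfamilies))
                NULL else as_tibble(associated_subfamilies),
              background_subfamilies = as.integer(background_subfamilies),
              archetypes = archetypes,
              residue_mutation_rate = residue_mutation_rate,
              cross_genus_identical = isTRUE(cross_genus_identical),
              subfamily_mutation_rate = subfamily_mutation_rate,
              radius = as.integer(radius))
  validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

validate_synth_config <- function(cfg) {
  for (f in c("n_contigs", "genes_per_contig", "background_subfamilies")) {
    if (!is_count(cfg[[f]]) || cfg[[f]] < 1) {
      cld_abort(paste0("`", f, "` must be a positive integer."),
                "config_error")
    }
  }
  if (!is_count(cfg$n_anchors)) {
    cld_abort("`n_anchors` must be a non-negative integer.", "config_error")
  }
  if (cfg$n_anchors > cfg$n_contigs * cfg$genes_per_contig) {
    cld_abort("`n_anchors` exceeds the total number of gene slots.",
              "config_error")
  }
  if (!is_prob(cfg$residue_mutation_rate)) {
    cld_abort("`residue_mutation_rate` must lie in [0, 1].", "config_error")
  }
  if (!is_prob(cfg$subfamily_mutation_rate)) {
    cld_abort("`subfamily_mutation_rate` must lie in [0, 1].", "config_error")
  }
  if (!is.null(cfg$associated_subfamilies)) {
    a <- cfg$associated_subfamilies
    need <- c("subfamily_id", "prob", "offset_range")
    if (!all(need %in% names(a))) {
      cld_abort("`associated_subfamilies` needs columns subfamily_id, prob, offset_range.",
                "config_error")
    }
    if (!is_prob(a$prob)) {
      cld_abort("`associated_subfamilies$prob` must lie in [0, 1].",
                "config_error")
    }
    if (any(a$offset_range < 1)) {
      cld_abort("`associated_subfamilies$offset_range` must be >= 1.",
                "config_error")
    }
  }
  invisible(cfg)
}

mutate_sequence <- function(seq, positions) {
  if (length(positions) == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  for (p in positions) {
    chars[p] <- sample(setdiff(AA_ALPHABET20, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

random_protein <- function(len) {
  paste(sample(AA_ALPHABET20, len, replace = TRUE), collapse = "")
}

#' Generate a synthetic comparative-genomics dataset
#'
#' Emits a mutually consistent gene table, protein FASTA, Cld family
#' alignment (reference plus all planted cld proteins), Newick tree over
#' the cld proteins, and a ground-truth record. Identical configurations
#' (including the seed) produce byte-identical outputs.
#'
#' Anchors are distributed round-robin across contigs and placed at
#' deterministic jittered positions. Each associated subfamily is planted,
#' with its configured probability, at a uniformly chosen non-anchor slot
#' within `offset_range` positions of each anchor. Flanking genes within
#' the neighborhood radius of an anchor draw their subfamily from the
#' anchor's archetype repertoire when archetypes are configured; all other
#' genes draw from the background subfamilies. Every subfamily has a fixed
#' random template sequence and members are point-mutated copies of it;
#' cld proteins are copies of the fixed Cld template whose key residues are
#' mutated with probability `residue_mutation_rate` (one uniformly chosen
#' key residue is lost).
#'
#' @param config A [synth_config()].
#' @param dir Optional directory; when supplied, all outputs are written
#'   there (`genes.gff3`, `genes.tsv`, `proteins.faa`, `cld_aligned.afa`,
#'   `cld_tree.nwk`, `truth_anchors.tsv`, `truth_subfamilies.tsv`).
#' @return A list with elements `genes` (indexed gene table tibble),
#'   `proteins` (named character vector), `alignment` (named character
#'   vector: reference + cld proteins), `tree` (`phylo` or `NULL` when
#'   fewer than 2 anchors), `truth` (list with `anchors` and
#'   `gene_subfamilies` tibbles), `config`, and `paths` (when `dir` was
#'   given).
#' @export
generate_dataset <- function(config, dir = NULL) {
  validate_synth_config(config)
  cfg <- config
  withr::with_seed(derive_seed(cfg$seed, 1L), {
    dataset <- build_synth_tables(cfg)
  })
  withr::with_seed(derive_seed(cfg$seed, 2L), {
    dataset <- build_synth_sequences(cfg, dataset)
  })
  withr::with_seed(derive_seed(cfg$seed, 3L), {
    dataset$tree <- build_synth_tree(dataset)
  })
  dataset$config <- cfg
  if (!is.null(dir)) {
    dataset$paths <- write_synth_dataset(dataset, dir)
  }
  dataset
}

build_synth_tables <- function(cfg) {
  n_genes <- cfg$n_contigs * cfg$genes_per_contig
  contig <- rep(seq_len(cfg$n_contigs), each = cfg$genes_per_contig)
  slot <- rep(seq_len(cfg$genes_per_contig), cfg$n_contigs) - 1L
  genes <- tibble(
    gene_id = sprintf("g_c%03d_%04d", contig, slot),
    protein_id = sprintf("p_c%03d_%04d", contig, slot),
    contig_id = sprintf("contig_%03d", contig),
    genome_id = sprintf("gnm_%03d", contig),
    start = slot * 1000L + 1L,
    end = slot * 1000L + 900L,
    strand = sample(c("+", "-"), n_genes, replace = TRUE)
  )
  genome_genus <- sample(GENUS_VOCAB, cfg$n_contigs, replace = TRUE)
  genome_phylum <- sample(PHYLUM_VOCAB, cfg$n_contigs, replace = TRUE)
  genome_source <- sample(c("genomic", "metagenomic"), cfg$n_contigs,
                          replace = TRUE, prob = c(0.7, 0.3))
  genes$genus <- genome_genus[contig]
  genes$phylum <- genome_phylum[contig]
  genes$source <- genome_source[contig]

  # Round-robin anchor placement with deterministic jitter; anchors on the
  # same contig are spaced by at least 2 * radius + 1 slots when room
  # allows, so planted windows do not collide.
  anchors_per_contig <- table(factor((seq_len(cfg$n_anchors) - 1L) %%
                                       cfg$n_contigs + 1L,
                                     levels = seq_len(cfg$n_contigs)))
  anchor_rows <- integer(0)
  for (ci in seq_len(cfg$n_contigs)) {
    k <- as.integer(anchors_per_contig[ci])
    if (k == 0) next
    spacing <- max(1L, min(2L * cfg$radius + 1L,
                           cfg$genes_per_contig %/% k))
    base <- (seq_len(k) - 1L) * spacing
    jitter_max <- max(0L, spacing - 1L)
    jit <- if (jitter_max > 0)
      sample.int(jitter_max + 1L, k, replace = TRUE) - 1L else rep(0L, k)
    pos <- pmin(base + jit, cfg$genes_per_contig - 1L)
    pos <- unique(pos)
    while (length(pos) < k) {
      extra <- setdiff(seq_len(cfg$genes_per_contig) - 1L, pos)
      pos <- c(pos, extra[sample.int(length(extra), 1L)])
    }
    anchor_rows <- c(anchor_rows, (ci - 1L) * cfg$genes_per_contig +
                       sort(pos) + 1L)
  }
  is_anchor <- seq_len(n_genes) %in% anchor_rows

  lineage <- sample(1:2, length(anchor_rows), replace = TRUE)
  subfam <- character(n_genes)
  subfam[anchor_rows] <- paste0("cld_", lineage)

  arch_names <- if (is.null(cfg$archetypes)) NULL else {
    nm <- names(cfg$archetypes)
    if (is.null(nm)) paste0("arch_", seq_along(cfg$archetypes)) else nm
  }
  anchor_arch <- if (is.null(cfg$archetypes)) rep(NA_character_,
                                                  length(anchor_rows))
    else arch_names[(seq_along(anchor_rows) - 1L) %%
                      length(cfg$archetypes) + 1L]

  # Archetype windows: flanks within `radius` slots of an anchor draw from
  # the anchor's repertoire.
  arch_of_gene <- rep(NA_character_, n_genes)
  for (ai in seq_along(anchor_rows)) {
    row <- anchor_rows[ai]
    ci <- contig[row]
    sl <- slot[row]
    win <- which(contig == ci & abs(slot - sl) <= cfg$radius)
    win <- setdiff(win, anchor_rows)
    arch_of_gene[win] <- anchor_arch[ai]
  }
  bg_pool <- paste0("bg_", seq_len(cfg$background_subfamilies))
  for (i in which(!is_anchor)) {
    subfam[i] <- if (!is.na(arch_of_gene[i])) {
      rep_pool <- cfg$archetypes[[arch_of_gene[i]]]
      rep_pool[sample.int(length(rep_pool), 1L)]
    } else {
      bg_pool[sample.int(length(bg_pool), 1L)]
    }
  }

  # Planted associated subfamilies: per anchor, with probability `prob`,
  # overwrite one non-anchor slot within `offset_range` of the anchor.
  # The acceptance/rejection uniform is drawn for every (anchor, subfamily)
  # pair regardless of outcome, so runs with different probabilities but
  # the same seed are coupled.
  if (!is.null(cfg$associated_subfamilies)) {
    a <- cfg$associated_subfamilies
    for (si in seq_len(nrow(a))) {
      for (ai in seq_along(anchor_rows)) {
        u <- stats::runif(1)
        row <- anchor_rows[ai]
        ci <- contig[row]
        sl <- slot[row]
        cand <- which(contig == ci & abs(slot - sl) <= a$offset_range[si])
        cand <- setdiff(cand, anchor_rows)
        if (u < a$prob[si] && length(cand) > 0) {
          subfam[cand[sample.int(length(cand), 1L)]] <- a$subfamily_id[si]
        }
      }
    }
  }

  anchors <- tibble(
    gene_id = genes$gene_id[anchor_rows],
    protein_id = genes$protein_id[anchor_rows],
    contig_id = genes$contig_id[anchor_rows],
    lineage = lineage,
    archetype = anchor_arch,
    genus = genes$genus[anchor_rows]
  )
  list(genes = genes,
       truth = list(
         anchors = anchors,
         gene_subfamilies = tibble(gene_id = genes$gene_id,
                                   protein_id = genes$protein_id,
                                   true_subfamily = subfam)
       ))
}

build_synth_sequences <- function(cfg, dataset) {
  subfam <- dataset$truth$gene_subfamilies
  anchors <- dataset$truth$anchors
  non_cld_ids <- setdiff(unique(subfam$true_subfamily),
                         c("cld_1", "cld_2"))
  templates <- stats::setNames(
    vapply(non_cld_ids, function(s) {
      random_protein(sample(150:300, 1L))
    }, character(1)), non_cld_ids)

  proteins <- character(nrow(subfam))
  names(proteins) <- subfam$protein_id
  is_cld <- subfam$true_subfamily %in% c("cld_1", "cld_2")
  for (i in which(!is_cld)) {
    tmpl <- templates[[subfam$true_subfamily[i]]]
    len <- nchar(tmpl)
    n_mut <- stats::rbinom(1, len, cfg$subfamily_mutation_rate)
    pos <- if (n_mut > 0) sample.int(len, n_mut) else integer(0)
    proteins[i] <- mutate_sequence(tmpl, pos)
  }

  # Cld proteins: template copies; with probability residue_mutation_rate
  # one uniformly chosen key residue is lost. Background mutations avoid
  # the key positions so residue truth is exact. The loss-decision uniform
  # is drawn first so rates are coupled across runs of the same seed.
  key_pos <- unname(CLD_KEY_POSITIONS)
  n_anch <- nrow(anchors)
  n_key <- integer(n_anch)
  cld_seqs <- character(n_anch)
  len <- nchar(CLD_TEMPLATE)
  loss_u <- stats::runif(n_anch)
  for (ai in seq_len(n_anch)) {
    lose <- loss_u[ai] < cfg$residue_mutation_rate
    which_key <- key_pos[sample.int(length(key_pos), 1L)]
    bg_sites <- setdiff(seq_len(len), key_pos)
    n_mut <- stats::rbinom(1, length(bg_sites), 0.02)
    pos <- if (n_mut > 0) bg_sites[sample.int(length(bg_sites), n_mut)]
      else integer(0)
    s <- mutate_sequence(CLD_TEMPLATE, pos)
    # the key-residue mutation is always drawn so identical seeds stay
    # coupled across different mutation rates
    s_lost <- mutate_sequence(s, which_key)
    cld_seqs[ai] <- if (lose) s_lost else s
    n_key[ai] <- if (lose) 3L else 4L
  }

  if (cfg$cross_genus_identical && nrow(anchors) >= 2) {
    # duplicate one intact sequence verbatim under a different genus
    donor <- which(n_key == 4L)[1]
    if (!is.na(donor)) {
      other <- setdiff(seq_len(nrow(anchors)), donor)
      recip <- other[1]
      cld_seqs[recip] <- cld_seqs[donor]
      n_key[recip] <- n_key[donor]
      if (anchors$genus[recip] == anchors$genus[donor]) {
        new_genus <- setdiff(GENUS_VOCAB, anchors$genus[donor])[1]
        anchors$genus[recip] <- new_genus
        dataset$genes$genus[dataset$genes$contig_id ==
                              anchors$contig_id[recip]] <- new_genus
      }
    }
  }
  proteins[anchors$protein_id] <- cld_seqs
  anchors$n_key_residues <- n_key
  dataset$truth$anchors <- anchors
  dataset$proteins <- proteins
  # equal-length template copies: the alignment is the sequences as-is
  dataset$alignment <- c(stats::setNames(CLD_TEMPLATE, CLD_REFERENCE_ID),
                         stats::setNames(cld_seqs, anchors$protein_id))
  dataset
}

build_synth_tree <- function(dataset) {
  ids <- dataset$truth$anchors$protein_id
  if (length(ids) < 2) return(NULL)
  ape::rcoal(length(ids), tip.label = ids)
}

write_synth_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    gff3 = file.path(dir, "genes.gff3"),
    genes_tsv = file.path(dir, "genes.tsv"),
    proteins = file.path(dir, "proteins.faa"),
    alignment = file.path(dir, "cld_aligned.afa"),
    tree = file.path(dir, "cld_tree.nwk"),
    truth_anchors = file.path(dir, "truth_anchors.tsv"),
    truth_subfamilies = file.path(dir, "truth_subfamilies.tsv")
  )
  write_gff3(dataset$genes, paths$gff3)
  readr::write_tsv(dataset$genes[, GENE_TABLE_COLS], paths$genes_tsv)
  write_fasta(dataset$proteins, paths$proteins)
  write_fasta(dataset$alignment, paths$alignment)
  if (!is.null(dataset$tree)) {
    ape::write.tree(dataset$tree, file = paths$tree)
  } else {
    paths$tree <- NULL
  }
  readr::write_tsv(dataset$truth$anchors, paths$truth_anchors)
  readr::write_tsv(dataset$truth$gene_subfamilies, paths$truth_subfamilies)
  paths
}

# Minimal deterministic writers (byte-stable across runs).
write_fasta <- function(seqs, path) {
  lines <- as.vector(rbind(paste0(">", names(seqs)), unname(seqs)))
  writeLines(lines, path)
  invisible(path)
}

write_gff3 <- function(genes, path) {
  attrs <- sprintf(
    "ID=%s;protein_id=%s;genome_id=%s;genus=%s;phylum=%s;sample_source=%s",
    genes$gene_id, genes$protein_id, genes$genome_id, genes$genus,
    genes$phylum, genes$source)
  lines <- sprintf("%s\tcldatlas_synth\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                   genes$contig_id, genes$start, genes$end, genes$strand,
                   attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
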