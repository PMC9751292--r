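#' Assemble a pipeline run configuration
#'
#' Collects every input path and stage parameter for [run_cld_pipeline()].
#' All paths are checked to exist up front; a missing path is a
#' configuration error raised before any stage runs.
#'
#' @param genes Path to the gene table (GFF3 or TSV).
#' @param alignment Path to the family alignment (aligned FASTA) including
#'   the reference sequence.
#' @param reference_id Reference sequence id in the alignment.
#' @param out_dir Output directory (created if absent).
#' @param proteins Optional protein FASTA for the native subfamily
#'   clusterer (required unless `clusters` is given).
#' @param clusters Optional representative-member cluster TSV; when given
#'   it is authoritative and the native clusterer is not run.
#' @param tree Optional rooted Newick tree over the identified Cld.
#' @param cld_lineages Optional TSV (`protein_id`, `lineage` 1/2) used to
#'   pin the Cld subfamily ids; Cld default to lineage 1 when absent.
#' @param signal_peptides Optional signal-peptide TSV.
#' @param hmm_table,hmm_dialect Optional HMMER table (and dialect) for the
#'   reductase screen.
#' @param env_counts Optional per-environment gene-count TSV
#'   (`environment`, `n_genes`, `n_cld`).
#' @param radius Neighborhood half-width (default 10 genes).
#' @param clade_threshold Mean-distance threshold for clade partitioning.
#' @param hit_threshold Clustering-coefficient hit threshold (default 0.1).
#' @param min_genes Minimum neighborhood size for grouping (default 10).
#' @param seed Seed for the stochastic embedding.
#' @param perplexity,iterations,distance,min_samples Grouping parameters
#'   (see [embed_and_group()]).
#' @param evalue_cutoff Reductase-screen E-value cutoff (default 1e-5).
#' @return A validated `cld_run_config` list.
#' @export
cld_run_config <- function(genes, alignment, reference_id, out_dir,
                           proteins = NULL, clusters = NULL, tree = NULL,
                           cld_lineages = NULL, signal_peptides = NULL,
                           hmm_table = NULL, hmm_dialect = "tblout",
                           env_counts = NULL, radius = 10L,
                           clade_threshold = 1, hit_threshold = 0.1,
                           min_genes = 10L, seed = 17L, perplexity = 50,
                           iterations = 5000L, distance = 4,
                           min_samples = 5L, evalue_cutoff = 1e-5) {
  cfg <- list(genes = genes, alignment = alignment,
              reference_id = reference_id, out_dir = out_dir,
              proteins = proteins, clusters = clusters, tree = tree,
              cld_lineages = cld_lineages,
              signal_peptides = signal_peptides, hmm_table = hmm_table,
              hmm_dialect = hmm_dialect, env_counts = env_counts,
              radius = as.integer(radius),
              clade_threshold = clade_threshold,
              hit_threshold = hit_threshold,
              min_genes = as.integer(min_genes), seed = as.integer(seed),
              perplexity = perplexity, iterations = as.integer(iterations),
              distance = distance, min_samples = as.integer(min_samples),
              evalue_cutoff = evalue_cutoff)
  path_fields <- c("genes", "alignment", "proteins", "clusters", "tree",
                   "cld_lineages", "signal_peptides", "hmm_table",
                   "env_counts")
  for (f in path_fields) {
    p <- cfg[[f]]
    if (!is.null(p) && !file.exists(p)) {
      cld_abort(paste0("Configured input `", f, "` does not exist: ", p),
                "config_error")
    }
  }
  if (is.null(cfg$proteins) && is.null(cfg$clusters)) {
    cld_abort("Either `proteins` or `clusters` must be supplied.",
              "config_error")
  }
  class(cfg) <- "cld_run_config"
  cfg
}

#' Run the full comparative-genomics pipeline
#'
#' Executes the stages in dependency order: Cld identification from the
#' alignment, neighborhood extraction around the identified *cld* genes,
#' subfamily assignment (imported or native), co-occurrence-network
#' linkage ranking, neighborhood grouping (when enough neighborhoods
#' qualify), and - independently - clade partitioning, the reductase
#' screen, and environment frequency metrics for whichever optional inputs
#' are configured. Every stage writes a TSV under `out_dir`, and a JSON
#' manifest records parameters, input checksums and outputs. Rerunning an
#' identical configuration reproduces all outputs byte-identically (the
#' manifest differs only in its timestamp).
#'
#' @param config A [cld_run_config()].
#' @return The manifest, invisibly (a list; also written as
#'   `manifest.json`).
#' @export
run_cld_pipeline <- function(config) {
  if (!inherits(config, "cld_run_config")) {
    cld_abort("`config` must be built with cld_run_config().",
              "config_error")
  }
  cfg <- config
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  outputs <- list()
  stages <- list()
  out <- function(name) file.path(cfg$out_dir, name)
  emit <- function(stage, df, name) {
    readr::write_tsv(df, out(name))
    outputs[[stage]] <<- c(outputs[[stage]], out(name))
  }
  run_stage <- function(stage, fun) {
    res <- tryCatch(fun(), error = function(e) {
      writeLines(paste0("stage=", stage, " failed: ", conditionMessage(e)),
                 out("FAILED"))
      cld_abort(paste0("Stage '", stage, "' failed: ",
                       conditionMessage(e)), "stage_error")
    })
    stages[[stage]] <<- list(status = "ok")
    res
  }

  # identify
  calls <- run_stage("identify", function() {
    aln <- read_alignment(cfg$alignment)
    sp <- if (!is.null(cfg$signal_peptides))
      read_signal_peptides(cfg$signal_peptides) else NULL
    cld_calls(aln, cfg$reference_id, signal_peptides = sp)
  })
  emit("identify", calls, "cld_calls.tsv")

  genes <- read_gene_table(cfg$genes)
  cld_proteins <- calls$protein_id[calls$is_cld]
  anchor_ids <- genes$gene_id[genes$protein_id %in% cld_proteins]

  # neighborhoods
  nbh <- run_stage("neighborhoods", function() {
    if (length(anchor_ids) == 0) {
      cld_abort("No cld anchors identified in the gene table.",
                "empty_input")
    }
    extract_neighborhoods(genes, anchor_ids, radius = cfg$radius)
  })
  emit("neighborhoods", nbh, "neighborhoods.tsv")

  # subfamilies
  assignment <- run_stage("subfamilies", function() {
    asg <- if (!is.null(cfg$clusters)) {
      import_cluster_tsv(cfg$clusters)
    } else {
      prot <- Biostrings::readAAStringSet(cfg$proteins)
      member_ids <- unique(nbh$protein_id)
      greedy_cluster(prot[names(prot) %in% member_ids])
    }
    lineages <- if (!is.null(cfg$cld_lineages)) {
      readr::read_tsv(cfg$cld_lineages, col_types = readr::cols(
        protein_id = readr::col_character(),
        lineage = readr::col_integer()))
    } else {
      tibble(protein_id = cld_proteins,
             lineage = rep(1L, length(cld_proteins)))
    }
    force_cld_subfamilies(asg, lineages[lineages$protein_id %in%
                                          asg$protein_id, ])
  })
  emit("subfamilies", assignment, "subfamilies.tsv")

  # linkage
  linkage <- run_stage("linkage", function() {
    network <- build_network(nbh, assignment)
    rank_linkage(network, hit_threshold = cfg$hit_threshold)
  })
  emit("linkage", as_tibble(linkage), "linkage.tsv")

  # groups (needs enough qualifying neighborhoods for the embedding)
  pm <- presence_matrix(nbh, assignment, min_genes = cfg$min_genes)
  if (nrow(pm) >= floor(3 * cfg$perplexity) + 2) {
    grouping <- run_stage("groups", function() {
      embed_and_group(pm, seed = cfg$seed, perplexity = cfg$perplexity,
                      iterations = cfg$iterations,
                      distance = cfg$distance,
                      min_samples = cfg$min_samples)
    })
    emit("groups", as_tibble(grouping), "groups.tsv")
  } else {
    stages[["groups"]] <- list(
      status = "skipped",
      reason = paste0("only ", nrow(pm), " neighborhoods with >= ",
                      cfg$min_genes, " genes; embedding needs ",
                      floor(3 * cfg$perplexity) + 2))
  }

  # clades (independent; optional tree)
  if (!is.null(cfg$tree)) {
    partition <- run_stage("clades", function() {
      tr <- ape::read.tree(cfg$tree)
      partition_clades(tr, threshold = cfg$clade_threshold)
    })
    emit("clades", as_tibble(partition), "clades.tsv")
  }

  # reductase screen (independent; optional HMM table)
  if (!is.null(cfg$hmm_table)) {
    screen <- run_stage("screen", function() {
      gene_map <- genes[, c("protein_id", "genome_id")]
      hits <- parse_hmm_table(cfg$hmm_table, dialect = cfg$hmm_dialect,
                              protein_genomes = gene_map)
      cld_by_genome <- genes %>%
        dplyr::group_by(.data$genome_id) %>%
        dplyr::summarise(
          has_cld = any(.data$protein_id %in% cld_proteins),
          .groups = "drop")
      classify_genomes(cld_by_genome, hits,
                       evalue_cutoff = cfg$evalue_cutoff)
    })
    emit("screen", screen, "screen.tsv")
  }

  # frequency metrics (independent; optional counts)
  if (!is.null(cfg$env_counts)) {
    freq <- run_stage("frequency", function() {
      counts <- readr::read_tsv(cfg$env_counts, col_types = readr::cols(
        environment = readr::col_character(),
        n_genes = readr::col_double(),
        n_cld = readr::col_double()))
      environment_frequency(counts)
    })
    emit("frequency", freq, "frequency.tsv")
  }

  input_paths <- Filter(Negate(is.null),
                        cfg[c("genes", "alignment", "proteins", "clusters",
                              "tree", "cld_lineages", "signal_peptides",
                              "hmm_table", "env_counts")])
  manifest <- list(
    package = "cldatlas",
    version = as.character(utils::packageVersion("cldatlas")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = cfg[c("reference_id", "radius", "clade_threshold",
                       "hit_threshold", "min_genes", "seed", "perplexity",
                       "iterations", "distance", "min_samples",
                       "evalue_cutoff", "hmm_dialect")],
    inputs = lapply(input_paths, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    stages = stages,
    outputs = lapply(outputs, function(ps)
      lapply(ps, function(p)
        list(path = p, md5 = unname(tools::md5sum(p)))))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
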