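gff3_fixture <- function(rows) {
  path <- withr::local_tempfile(fileext = ".gff3",
                                .local_envir = parent.frame())
  writeLines(c("##gff-version 3", rows), path)
  path
}

gff3_row <- function(contig, start, end, id, strand = "+") {
  sprintf("%s\tsynth\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;protein_id=p_%s;genome_id=gnm1",
          contig, start, end, strand, id, id)
}

test_that("genes are sorted by coordinate and indexed per contig", {
  path <- gff3_fixture(c(gff3_row("c1", 10, 50, "gA"),
                         gff3_row("c1", 200, 260, "gB"),
                         gff3_row("c1", 90, 150, "gC")))
  genes <- read_gene_table(path)
  expect_equal(genes$index[match(c("gA", "gB", "gC"), genes$gene_id)],
               c(0L, 2L, 1L))
})

test_that("ties on start are broken by end then gene id", {
  path <- gff3_fixture(c(gff3_row("c1", 10, 90, "gB"),
                         gff3_row("c1", 10, 50, "gA"),
                         gff3_row("c1", 10, 50, "gC")))
  genes <- read_gene_table(path)
  expect_equal(genes$gene_id[order(genes$index)], c("gA", "gC", "gB"))
})

test_that("empty inputs give empty tables and duplicates are rejected", {
  path <- gff3_fixture(character(0))
  expect_equal(nrow(read_gene_table(path)), 0)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(cldatlas:::GENE_TABLE_COLS, collapse = "\t"), tsv)
  expect_equal(nrow(read_gene_table(tsv)), 0)

  dup <- gff3_fixture(c(gff3_row("c1", 10, 50, "gA"),
                        gff3_row("c1", 90, 150, "gA")))
  expect_error(read_gene_table(dup), "gA",
               class = "cldatlas_uniqueness_error")
})

test_that("TSV and GFF3 dialects produce the same indexed table", {
  d <- generate_dataset(synth_config(seed = 31, n_contigs = 3,
                                     genes_per_contig = 15, n_anchors = 3),
                        dir = withr::local_tempdir())
  from_gff <- read_gene_table(d$paths$gff3)
  from_tsv <- read_gene_table(d$paths$genes_tsv)
  cols <- c("gene_id", "protein_id", "contig_id", "start", "end", "strand",
            "index")
  expect_equal(as.data.frame(from_gff[cols]), as.data.frame(from_tsv[cols]))
})

test_that("windows truncate at contig boundaries", {
  genes <- tibble::tibble(
    gene_id = paste0("g", 1:100), protein_id = paste0("p", 1:100),
    contig_id = "c1", genome_id = "G", start = (1:100) * 100,
    end = (1:100) * 100 + 50, strand = "+")
  # anchor at index 15 (gene g16): full window
  full <- extract_neighborhoods(genes, "g16")
  expect_equal(nrow(full), 21)
  expect_equal(full$offset, -10:10)
  expect_equal(full$gene_id[full$offset == 0], "g16")
  # anchor at index 3: left truncation
  left <- extract_neighborhoods(genes, "g4")
  expect_equal(nrow(left), 14)
  expect_equal(left$offset, -3:10)
  # 5-gene contig, anchor at index 2: everything
  small <- genes[1:5, ]
  all5 <- extract_neighborhoods(small, "g3")
  expect_equal(nrow(all5), 5)
  expect_equal(all5$offset, -2:2)

  expect_error(extract_neighborhoods(genes, "nope"),
               class = "cldatlas_lookup_error")
})

test_that("identical member sets are deduplicated keeping the first anchor", {
  genes <- tibble::tibble(
    gene_id = paste0("g", 1:5), protein_id = paste0("p", 1:5),
    contig_id = "c1", genome_id = "G", start = (1:5) * 100,
    end = (1:5) * 100 + 50, strand = "+")
  # both anchors see the whole 5-gene contig -> one neighborhood survives
  nbh <- extract_neighborhoods(genes, c("g2", "g4"))
  expect_equal(length(unique(nbh$neighborhood_id)), 1)
  expect_equal(unique(nbh$anchor_gene_id), "g2")
  # larger contig: overlapping but distinct member sets are both kept
  genes2 <- tibble::tibble(
    gene_id = paste0("g", 1:40), protein_id = paste0("p", 1:40),
    contig_id = "c1", genome_id = "G", start = (1:40) * 100,
    end = (1:40) * 100 + 50, strand = "+")
  nbh2 <- extract_neighborhoods(genes2, c("g15", "g20"))
  expect_equal(length(unique(nbh2$neighborhood_id)), 2)
})

test_that("neighborhoods round-trip through TSV exactly", {
  d <- generate_dataset(synth_config(seed = 17, n_contigs = 4,
                                     genes_per_contig = 30, n_anchors = 4))
  nbh <- extract_neighborhoods(d$genes, d$truth$anchors$gene_id)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_neighborhoods(nbh, path)
  back <- read_neighborhoods(path)
  expect_equal(as.data.frame(back), as.data.frame(nbh))
})

test_that("member offsets stay within the radius and planted genes are captured", {
  d <- generate_dataset(synth_config(
    seed = 23, n_contigs = 10, genes_per_contig = 30, n_anchors = 10,
    associated_subfamilies = tibble::tibble(subfamily_id = "S", prob = 1,
                                            offset_range = 3)))
  for (radius in c(3L, 10L)) {
    nbh <- extract_neighborhoods(d$genes, d$truth$anchors$gene_id,
                                 radius = radius)
    expect_true(all(abs(nbh$offset) <= radius))
  }
  nbh <- extract_neighborhoods(d$genes, d$truth$anchors$gene_id)
  sub <- d$truth$gene_subfamilies
  s_proteins <- sub$protein_id[sub$true_subfamily == "S"]
  for (id in unique(nbh$neighborhood_id)) {
    members <- nbh$protein_id[nbh$neighborhood_id == id]
    expect_gte(sum(members %in% s_proteins), 1)
  }
})
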