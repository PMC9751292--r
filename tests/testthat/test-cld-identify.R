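test_that("reference positions map through gaps to alignment columns", {
  aln <- c(ref = "MA-RK", q = "MAQRK")
  rmap <- map_reference_residues(aln, key_residue_spec("ref", 3, "R"))
  expect_equal(rmap$column, 4L)

  # no gaps in the reference: column equals position
  aln2 <- c(ref = "MARKHE", q = "MARKHE")
  spec2 <- key_residue_spec("ref", c(2, 4, 5, 6), c("A", "K", "H", "E"))
  expect_equal(map_reference_residues(aln2, spec2)$column, c(2L, 4L, 5L, 6L))
})

test_that("mapping errors are typed and informative", {
  aln <- c(ref = "MARK", q = "MARK")
  expect_error(map_reference_residues(aln, key_residue_spec("nope", 1, "M")),
               class = "cldatlas_missing_reference")
  expect_error(map_reference_residues(aln, key_residue_spec("ref", 127, "R")),
               "127", class = "cldatlas_range_error")
  expect_error(map_reference_residues(aln, key_residue_spec("ref", 2, "W")),
               class = "cldatlas_spec_mismatch")
  expect_error(key_residue_spec("ref", c(3, 2), c("R", "A")),
               class = "cldatlas_parameter_error")
  expect_error(key_residue_spec("ref", 2, "J"),
               class = "cldatlas_parameter_error")
})

test_that("key residues are counted by exact match and gaps never match", {
  aln <- c(ref = "MKAHARAE",
           same = "MKAHARAE",
           one_off = "MKAHARAQ",   # E -> Q at the last key column
           gapped = "M-A-A-A-")
  spec <- key_residue_spec("ref", c(2, 4, 6, 8), c("K", "H", "R", "E"))
  rmap <- map_reference_residues(aln, spec)
  counts <- count_key_residues(aln, rmap)
  expect_equal(counts$n_key_residues[counts$protein_id == "ref"], 4L)
  expect_equal(counts$n_key_residues[counts$protein_id == "same"], 4L)
  expect_equal(counts$n_key_residues[counts$protein_id == "one_off"], 3L)
  expect_equal(counts$n_key_residues[counts$protein_id == "gapped"], 0L)
  expect_equal(counts$n_key_gaps[counts$protein_id == "gapped"], 4L)
  expect_error(count_key_residues(aln, rmap, ids = "missing"),
               class = "cldatlas_missing_sequence")
  # ambiguity codes never match
  aln_x <- c(ref = "MKAHARAE", amb = "MXAXAXAX")
  expect_equal(count_key_residues(aln_x, rmap)$n_key_residues[2], 0L)
})

test_that("classification requires all key residues", {
  expect_true(classify_cld(4L))
  expect_false(classify_cld(3L))
  expect_false(classify_cld(0L))
  expect_equal(classify_cld(c(4, 2, 4)), c(TRUE, FALSE, TRUE))
  expect_error(classify_cld(5L), class = "cldatlas_parameter_error")
})

test_that("counting is invariant under appended gap-only columns", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      n <- sample(3:8, 1)
      width <- sample(10:30, 1)
      aln <- setNames(vapply(seq_len(n), function(i) {
        paste(sample(c(cldatlas:::AA_ALPHABET20, "-"), width, replace = TRUE),
              collapse = "")
      }, character(1)), paste0("p", seq_len(n)))
      aln[1] <- strrep("A", width) # gapless all-A reference
      spec <- key_residue_spec("p1", sort(sample(width, 3)),
                               c("A", "A", "A"))
      rmap <- map_reference_residues(aln, spec)
      padded <- setNames(paste0(aln, "---"), names(aln))
      expect_equal(count_key_residues(aln, rmap)$n_key_residues,
                   count_key_residues(padded,
                                      map_reference_residues(
                                        padded, spec))$n_key_residues)
    }
  })
})

test_that("terminal extensions follow the mean occupied span", {
  # identical spans: all extensions zero
  aln <- c(a = "AAAAAAAA", b = "CCCCCCCC", c = "DDDDDDDD")
  ext <- terminal_extensions(aln, names(aln))
  expect_true(all(ext$n_term_extension == 0))
  expect_true(all(ext$c_term_extension == 0))
  expect_false(any(ext$long_extension_flag))

  # starts at columns 1, 1, 7: mean start 3; early starters carry 2
  # residues before column 3, the late starter 0
  aln2 <- c(a = "AAAAAAAAAAAA",
            b = "CCCCCCCCCCCC",
            c = "------DDDDDD")
  ext2 <- terminal_extensions(aln2, names(aln2))
  expect_equal(attr(ext2, "mean_start_column"), 3L)
  expect_equal(ext2$n_term_extension, c(2L, 2L, 0L))
  expect_equal(ext2$c_term_extension, c(0L, 0L, 0L))

  # an extension longer than 20 residues raises the flag
  long <- paste(rep("A", 25), collapse = "")
  core <- paste(rep("C", 10), collapse = "")
  aln3 <- c(x = paste0(long, core),
            y = paste0(strrep("-", 25), core),
            z = paste0(strrep("-", 25), core))
  ext3 <- terminal_extensions(aln3, names(aln3))
  # mean start = round((1 + 26 + 26) / 3) = 18 -> x has 17 residues before
  expect_equal(attr(ext3, "mean_start_column"), 18L)
  expect_equal(ext3$n_term_extension[1], 17L)
  aln4 <- c(x = paste0(long, core),
            y = paste0(strrep("-", 25), core),
            z = paste0(strrep("-", 25), core),
            w = paste0(strrep("-", 25), core),
            v = paste0(strrep("-", 25), core))
  ext4 <- terminal_extensions(aln4, names(aln4))
  # mean start = round((1 + 4 * 26) / 5) = 21 -> x has 20 before: not long;
  # with threshold 19 it is flagged
  expect_equal(ext4$n_term_extension[1], 20L)
  expect_false(ext4$long_extension_flag[1])
  expect_true(terminal_extensions(aln4, names(aln4),
                                  long_threshold = 19)$long_extension_flag[1])

  expect_error(terminal_extensions(aln, character(0)),
               class = "cldatlas_empty_input")
})

test_that("calls agree with synthetic truth when mutations target key columns", {
  d <- generate_dataset(synth_config(seed = 8, n_contigs = 20,
                                     genes_per_contig = 10, n_anchors = 40,
                                     residue_mutation_rate = 0.4))
  calls <- cld_calls(d$alignment, "Nwinogradskyi_ref")
  truth <- d$truth$anchors
  got <- calls[match(truth$protein_id, calls$protein_id), ]
  expect_equal(got$n_key_residues, truth$n_key_residues)
  expect_equal(got$is_cld, truth$n_key_residues == 4L)
  expect_equal(calls$n_key_residues[calls$protein_id == "Nwinogradskyi_ref"],
               4L)
})

test_that("fraction of intact proteins is monotone non-increasing in the mutation rate", {
  rates <- c(0, 0.25, 0.5, 0.75, 1)
  frac <- vapply(rates, function(r) {
    d <- generate_dataset(synth_config(seed = 13, n_contigs = 25,
                                       genes_per_contig = 20,
                                       n_anchors = 500,
                                       residue_mutation_rate = r))
    calls <- cld_calls(d$alignment, "Nwinogradskyi_ref")
    anchors <- calls[calls$protein_id != "Nwinogradskyi_ref", ]
    mean(anchors$n_key_residues == 4L)
  }, numeric(1))
  expect_true(all(diff(frac) <= 0))
  expect_equal(frac[1], 1)
  expect_equal(frac[5], 0)
})

test_that("signal peptide annotations are merged, never computed", {
  aln <- c(ref = "MKAHARAE", p1 = "MKAHARAE", p2 = "MKAHARAQ")
  spec <- key_residue_spec("ref", c(2, 4, 6, 8), c("K", "H", "R", "E"))
  sp <- tibble::tibble(protein_id = "p1", signal_peptide = TRUE)
  calls <- cld_calls(aln, "ref", spec = spec, signal_peptides = sp)
  expect_true(calls$signal_peptide[calls$protein_id == "p1"])
  expect_true(is.na(calls$signal_peptide[calls$protein_id == "p2"]))
  expect_true(calls$is_cld[calls$protein_id == "p1"])
  expect_false(calls$is_cld[calls$protein_id == "p2"])
})
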