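write_fasta_records <- function(headers, seqs) {
  f <- withr::local_tempfile(fileext = ".fa", .local_envir = parent.frame())
  writeLines(paste0(">", headers, "\n", seqs), f)
  f
}

test_that("collapsed FASTA reads merge identical sequences with summed counts", {
  s <- "ACGTACGTACGTACGTACGT"
  f <- write_fasta_records(c("a_x3", "b_x2"), c(s, s))
  lr <- load_reads(f, "fasta_collapsed")
  expect_equal(unname(lr$counts[s]), 5L)
  expect_length(lr$counts, 1)
})

test_that("FASTQ and raw FASTA records each count once", {
  s <- "ACGTACGTACGTACGTACGT"
  fq <- withr::local_tempfile(fileext = ".fq")
  writeLines(rep(c("@r", s, "+", strrep("I", nchar(s))), 4), fq)
  lr <- load_reads(fq, "fastq")
  expect_equal(unname(lr$counts[s]), 4L)
  f <- write_fasta_records(c("r1", "r2"), c(s, "AAAACCCCGGGGTTTTAAAA"))
  lr2 <- load_reads(f, "fasta_raw")
  expect_equal(unname(lr2$counts[s]), 1L)
  expect_length(lr2$counts, 2)
})

test_that("sequences are case-folded and U-converted on load", {
  f <- write_fasta_records("r_x2", "acguACGU")
  lr <- load_reads(f, "fasta_collapsed")
  expect_identical(names(lr$counts), "ACGTACGT")
})

test_that("malformed records raise errors naming the record", {
  f <- write_fasta_records(c("ok_x1", "missing_count"),
                           c("ACGTACGT", "ACGTACGT"))
  expect_error(load_reads(f, "fasta_collapsed"), "record 2")
  f2 <- write_fasta_records("bad_x1", "ACGTNNGT")
  expect_error(load_reads(f2, "fasta_collapsed"), "record 1")
})

test_that("an empty read file warns and yields an empty library", {
  f <- withr::local_tempfile(fileext = ".fa")
  file.create(f)
  expect_warning(lr <- load_reads(f, "fasta_collapsed"), "empty")
  expect_length(lr$counts, 0)
})

test_that("the length filter keeps exactly the 18-28 nt range", {
  counts <- setNames(rep(1L, 4),
                     c(random_dna(1, 17), random_dna(1, 18),
                       random_dna(1, 28), random_dna(1, 29)))
  lr <- library_reads("t", "control", 1, counts)
  kept <- length_filter(lr)
  expect_setequal(nchar(names(kept$counts)), c(18, 28))
  expect_equal(unname(attr(kept, "removed")["total"]), 2)
  # identity when everything is in range; empty stays empty
  lr2 <- library_reads("t", "control", 1, setNames(3L, random_dna(1, 21)))
  expect_identical(length_filter(lr2)$counts, lr2$counts)
  lr0 <- library_reads("t", "control", 1, integer(0))
  expect_length(length_filter(lr0)$counts, 0)
  expect_error(length_filter(lr, min_len = 25, max_len = 20), "min_len")
})

test_that("the waterfall assigns the first matching tier", {
  set.seed(41)
  mature <- random_dna(1, 21)
  # the same sequence is embedded in a structural ncRNA AND is a catalog
  # mature: the ncRNA tier must win
  ncrna <- c(trna_1 = paste0(random_dna(1, 40), mature, random_dna(1, 40)))
  refs <- toy_refs(mature = c("syn-miR900a" = mature), ncrna = ncrna)
  other <- random_dna(1, 25)
  lr <- library_reads("t", "control", 1,
                      setNames(c(5L, 2L), c(mature, other)))
  ann <- annotate_waterfall(lr, refs)
  expect_equal(as.character(ann$category_of_read[[mature]]), "noncoding")
  expect_equal(as.character(ann$category_of_read[[other]]), "unmapped")
})

test_that("catalog matching honors the mismatch tolerance and records ids", {
  set.seed(43)
  mature <- random_dna(1, 21)
  refs <- toy_refs(mature = c("syn-miR900a" = mature))
  mut <- function(s, n) {
    v <- strsplit(s, "")[[1]]
    for (i in seq_len(n)) v[i] <- setdiff(c("A", "C", "G", "T"), v[i])[1]
    paste(v, collapse = "")
  }
  lr <- library_reads("t", "control", 1,
                      setNames(rep(1L, 3),
                               c(mature, mut(mature, 2), mut(mature, 3))))
  ann <- annotate_waterfall(lr, refs)
  expect_equal(as.character(ann$category_of_read[[mature]]), "mirbase")
  expect_equal(ann$matched_mirna_ids[[mature]], "syn-miR900a")
  expect_equal(as.character(ann$category_of_read[[mut(mature, 2)]]), "mirbase")
  expect_false(as.character(ann$category_of_read[[mut(mature, 3)]]) == "mirbase")
  # exact-match mode
  ann0 <- annotate_waterfall(lr, refs, mirbase_max_mismatch = 0)
  expect_equal(as.character(ann0$category_of_read[[mut(mature, 2)]]), "unmapped")
})

test_that("category tallies partition the library", {
  fx <- fixture_small()
  for (ann in fx$anns) {
    expect_equal(sum(ann$tally$total), sum(ann$counts))
    expect_equal(sum(ann$tally$unique), length(ann$counts))
    expect_true(all(ann$tally$unique <= ann$tally$total))
  }
  tt <- tally_table(fx$anns)
  for (lib in names(fx$libs)) {
    col <- paste0("total_", lib)
    expect_equal(tt[[col]][tt$category == "Total"],
                 sum(tt[[col]][tt$category != "Total"]))
    expect_equal(tt[[col]][tt$category == "Total"], fx$cfg$library_depth)
  }
  expect_s3_class(attr(tt, "genome_any_tier"), "data.frame")
})

test_that("genome-category membership is strand-symmetric", {
  set.seed(47)
  genome <- c(chr1 = random_dna(1, 3000))
  refs <- reference_set(genome = genome)
  refs_rc <- reference_set(genome = c(chr1 = revcomp(genome)))
  pos <- seq(1, 2900, by = 250)
  reads <- substring(genome, pos, pos + 20)
  reads <- c(reads, random_dna(3, 21))  # some unmapped
  lr <- library_reads("t", "control", 1, setNames(rep(1L, length(reads)), reads))
  a1 <- suppressWarnings(annotate_waterfall(lr, refs))
  a2 <- suppressWarnings(annotate_waterfall(lr, refs_rc))
  expect_identical(a1$category_of_read, a2$category_of_read)
})

test_that("tier order, not reference insertion order, decides categories", {
  fx <- fixture_small()
  refs <- fx$refs
  refs_perm <- reference_set(
    genome = refs$genome,
    structural_ncrna = rev(refs$structural_ncrna),
    repeats_mrna = rev(refs$repeats_mrna),
    mature_catalog = rev(refs$mature_catalog))
  lr <- length_filter(fx$libs[[1]])
  a1 <- annotate_waterfall(lr, refs)
  a2 <- annotate_waterfall(lr, refs_perm)
  expect_identical(a1$category_of_read, a2$category_of_read)
})

test_that("planted matures are mirbase with the catalog, genome without it", {
  fx <- fixture_small()
  ann <- fx$anns[[1]]
  hp <- fx$truth$planted_hairpins
  for (m in hp$mature)
    expect_equal(as.character(ann$category_of_read[[m]]), "mirbase")
  refs_nocat <- reference_set(genome = fx$refs$genome,
                              structural_ncrna = fx$refs$structural_ncrna,
                              repeats_mrna = fx$refs$repeats_mrna)
  ann2 <- suppressWarnings(
    annotate_waterfall(length_filter(fx$libs[[1]]), refs_nocat))
  for (m in hp$mature)
    expect_equal(as.character(ann2$category_of_read[[m]]), "genome")
})
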