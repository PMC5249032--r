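test_that("genome mapping reports loci on both strands and drops repeats", {
  set.seed(81)
  genome <- c(chr1 = random_dna(1, 2000))
  r_fwd <- substr(genome, 501, 521)
  r_rev <- revcomp(substr(genome, 1001, 1024))
  absent <- random_dna(1, 25)
  loci <- map_unannotated(c(r_fwd, r_rev, absent), genome)
  expect_equal(loci$start[loci$read == r_fwd], 500)
  expect_equal(loci$end[loci$read == r_fwd], 521)
  expect_equal(loci$strand[loci$read == r_fwd], "+")
  expect_equal(loci$start[loci$read == r_rev], 1000)
  expect_equal(loci$strand[loci$read == r_rev], "-")
  expect_false(absent %in% loci$read)
  # poly-A read in a poly-A genome exceeds max_loci
  polyg <- c(chr1 = strrep("A", 200))
  l2 <- map_unannotated(strrep("A", 21), polyg, max_loci = 5)
  expect_equal(nrow(l2), 0)
  expect_equal(attr(l2, "repetitive"), strrep("A", 21))
})

test_that("precursor windows are symmetric, clipped and strand-aware", {
  set.seed(83)
  genome <- c(chr1 = random_dna(1, 3000))
  loc <- list(chrom = "chr1", start = 1000, end = 1021, strand = "+")
  pr <- extract_precursor(loc, genome)
  expect_equal(nchar(pr$precursor), 321)
  expect_equal(pr$window_start, 850)
  expect_equal(pr$window_end, 1171)
  expect_equal(substr(pr$precursor, pr$read_start, pr$read_end),
               substr(genome[["chr1"]], 1001, 1021))
  expect_false(pr$clipped)
  # clipping at the chromosome start
  loc2 <- list(chrom = "chr1", start = 10, end = 31, strand = "+")
  pr2 <- extract_precursor(loc2, genome)
  expect_equal(pr2$window_start, 0)
  expect_equal(pr2$window_end, 181)
  expect_true(pr2$clipped)
  # minus strand: precursor is the reverse complement of the window
  loc3 <- list(chrom = "chr1", start = 1000, end = 1021, strand = "-")
  pr3 <- extract_precursor(loc3, genome)
  expect_equal(pr3$precursor, revcomp(substr(genome[["chr1"]], 851, 1171)))
  expect_equal(substr(pr3$precursor, pr3$read_start, pr3$read_end),
               revcomp(substr(genome[["chr1"]], 1001, 1021)))
})

test_that("planted hairpins pass duplex evaluation with the planted mismatches", {
  fx <- fixture_discovery()
  hp <- fx$truth$planted_hairpins
  genome <- list(chr1 = fx$refs$genome[["chr1"]])
  for (i in seq_len(nrow(hp))) {
    loc <- list(chrom = "chr1", start = hp$mature_start[i],
                end = hp$mature_end[i], strand = "+")
    pr <- extract_precursor(loc, fx$refs$genome)
    ff <- hairpin_structure(pr$precursor, pr$read_start, pr$read_end)
    ev <- evaluate_duplex(ff, pr$read_start, pr$read_end)
    expect_true(ev$pass)
    expect_equal(ev$mismatches, fx$cfg$planted_mismatches)
    expect_equal(ev$arm, "5p")
    expect_lte(ev$bulge, 2)
  }
})

test_that("a mature read across the loop fails with a loop-spanning reason", {
  arm <- "ACGTGTCAGTACG"
  s <- paste0(arm, strrep("A", 12), revcomp(arm))
  mid <- nchar(arm) + 1
  f <- fold_back(s)
  ev <- evaluate_duplex(f, mid - 4, mid + 10)
  expect_false(ev$pass)
  expect_true(ev$reason %in% c("loop-spanning", "insufficient pairing"))
})

test_that("unstructured random windows never pass duplex evaluation", {
  set.seed(89)
  passes <- 0
  for (t in 1:50) {
    w <- random_dna(1, 321)
    ff <- hairpin_structure(w, 151, 171)
    if (evaluate_duplex(ff, 151, 171)$pass) passes <- passes + 1
  }
  expect_equal(passes, 0)
})

test_that("star search finds the planted star and rejects 3-nt offsets", {
  fx <- fixture_discovery()
  hp <- fx$truth$planted_hairpins
  i <- 1
  loc <- list(chrom = "chr1", start = hp$mature_start[i],
              end = hp$mature_end[i], strand = "+")
  pr <- extract_precursor(loc, fx$refs$genome)
  ff <- hairpin_structure(pr$precursor, pr$read_start, pr$read_end)
  lib_star <- list(library_reads("s", "control", 1,
                                 setNames(10L, hp$star[i])))
  st <- find_star(pr$precursor, ff, pr$read_start, pr$read_end, lib_star)
  expect_equal(st$sequence, hp$star[i])
  expect_equal(st$total, 10)
  # the same-length read shifted 3 nt along the precursor is not accepted
  pos <- regexpr(hp$star[i], pr$precursor, fixed = TRUE)
  shifted <- substr(pr$precursor, pos + 3, pos + 3 + nchar(hp$star[i]) - 1)
  lib_shift <- list(library_reads("s", "control", 1, setNames(10L, shifted)))
  expect_null(find_star(pr$precursor, ff, pr$read_start, pr$read_end,
                        lib_shift))
  # no star reads sequenced: no evidence
  lib_none <- list(library_reads("s", "control", 1,
                                 setNames(5L, random_dna(1, 21))))
  expect_null(find_star(pr$precursor, ff, pr$read_start, pr$read_end,
                        lib_none))
})

test_that("the full discovery run calls exactly the star-supported hairpins", {
  fx <- fixture_discovery()
  disc <- discover_novel(fx$anns, fx$refs, fx$libs)
  hp <- fx$truth$planted_hairpins
  expected <- hp$mature[hp$family_id %in% fx$star_families]
  expect_equal(nrow(disc$novel), length(expected))
  expect_setequal(disc$novel$read, expected)
  # determinism of the whole call set
  disc2 <- discover_novel(fx$anns, fx$refs, fx$libs)
  expect_identical(disc$novel, disc2$novel)
})

test_that("overlapping candidate loci merge into one call", {
  fx <- fixture_discovery()
  hp <- fx$truth$planted_hairpins
  i <- 1
  # an isomiR-like read: the planted mature shifted by 1 nt
  iso <- substr(fx$refs$genome[["chr1"]], hp$mature_start[i],
                hp$mature_start[i] + 21)
  reads <- setNames(c(50, 20), c(hp$mature[i], iso))
  cand <- hairpin_candidates(reads, fx$refs$genome, fx$libs, min_count = 1)
  called <- call_novel(cand)
  expect_equal(nrow(called), 1)
  expect_equal(called$read, hp$mature[i])  # most abundant kept
})

test_that("a candidate failing the duplex is not called even with a star", {
  cand <- empty <- mirpipe:::empty_candidates()
  cand[1, ] <- list("ACGT", 10, "chr1", 0L, 21L, "+", 0L, 100L, "SEQ", ".",
                    "5p", 6L, 0L, FALSE, "too many mismatches", "GGG", 5,
                    TRUE)
  expect_equal(nrow(call_novel(cand)), 0)
})

test_that("discovery is strand-consistent under genome reversal", {
  fx <- fixture_discovery()
  hp <- fx$truth$planted_hairpins
  L <- nchar(fx$refs$genome[["chr1"]])
  refs_rc <- reference_set(genome = c(chr1 = revcomp(fx$refs$genome[["chr1"]])))
  reads <- setNames(rep(10, 3), hp$mature[1:3])
  c1 <- hairpin_candidates(reads, fx$refs$genome, fx$libs, min_count = 1)
  c2 <- hairpin_candidates(reads, refs_rc$genome, fx$libs, min_count = 1)
  expect_equal(nrow(c1), nrow(c2))
  for (r in names(reads)) {
    r1 <- c1[c1$read == r, ]
    r2 <- c2[c2$read == r, ]
    expect_equal(r2$start, L - r1$end)
    expect_equal(r2$strand, "-")
    expect_equal(r2$precursor, r1$precursor)
    expect_equal(r1$pass_duplex, r2$pass_duplex)
  }
})
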