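test_that("config validation rejects inconsistent settings", {
  expect_error(sim_config(library_depth = 0), "library_depth")
  expect_error(sim_config(nb_dispersion = -1), "dispersion")
  expect_error(sim_config(mature_length = 30), "mature_length")
  expect_error(sim_config(length_peak_weights = c(`21` = 0.5, `24` = 0.4)),
               "sum to 1")
  expect_error(sim_config(n_hairpins = 3, n_families = 5), "n_families")
})

test_that("a hairpin-free genome carries only decoys", {
  cfg <- sim_config(n_hairpins = 0, n_families = 0, genome_length = 5000,
                    seed = 5)
  g <- generate_genome(cfg)
  expect_equal(nrow(g$truth$planted_hairpins), 0)
  expect_length(g$refs$mature_catalog, 0)
  expect_equal(nchar(g$refs$genome[["chr1"]]), 5000)
})

test_that("genome generation is seed-deterministic and capacity-checked", {
  cfg <- sim_config(n_hairpins = 5, genome_length = 20000, seed = 17)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1$refs, g2$refs)
  expect_identical(g1$truth$planted_hairpins, g2$truth$planted_hairpins)
  expect_error(generate_genome(sim_config(n_hairpins = 50, genome_length = 1000)),
               "too small")
})

test_that("planted matures occur exactly once in the genome and never in decoys", {
  fx <- fixture_small()
  genome <- fx$refs$genome[["chr1"]]
  for (m in fx$truth$planted_hairpins$mature) {
    n_fwd <- length(gregexpr(m, genome, fixed = TRUE)[[1]])
    hit_fwd <- regexpr(m, genome, fixed = TRUE) > 0
    hit_rev <- regexpr(revcomp(m), genome, fixed = TRUE) > 0
    expect_true(hit_fwd && !hit_rev && n_fwd == 1)
    for (d in c(fx$refs$structural_ncrna, fx$refs$repeats_mrna))
      expect_false(grepl(m, d, fixed = TRUE))
  }
})

test_that("planted star pairs the mature with the configured 3' overhang", {
  fx <- fixture_small()
  hp <- fx$truth$planted_hairpins
  ov <- fx$cfg$star_overhang
  k <- fx$cfg$planted_mismatches
  for (i in seq_len(nrow(hp))) {
    m <- strsplit(hp$mature[i], "")[[1]]
    s <- strsplit(hp$star[i], "")[[1]]
    L <- length(m)
    # star position t pairs mature position (L - ov) - t + 1
    dup <- vapply(seq_len(L - ov), function(t) {
      paste0(s[t], m[(L - ov) - t + 1])
    }, character(1))
    n_pair <- sum(dup %in% c("AT", "TA", "CG", "GC"))
    expect_equal((L - ov) - n_pair, k)
  }
})

test_that("library totals conserve the configured depth", {
  fx <- fixture_small()
  for (lr in fx$libs)
    expect_equal(sum(lr$counts), fx$cfg$library_depth)
})

test_that("library simulation is seed-deterministic", {
  fx <- fixture_small()
  libs2 <- simulate_libraries(fx$refs, fx$truth, fx$cfg)
  expect_identical(lapply(fx$libs, `[[`, "counts"),
                   lapply(libs2, `[[`, "counts"))
})

test_that("background read lengths follow the configured distribution", {
  cfg <- sim_config(n_hairpins = 0, n_families = 0, genome_length = 20000,
                    library_depth = 100000, replicates_per_condition = 1,
                    seed = 23)
  g <- generate_genome(cfg)
  libs <- simulate_libraries(g$refs, g$truth, cfg)
  lr <- libs[[1]]
  w <- nchar(names(lr$counts))
  obs <- vapply(as.integer(names(cfg$length_peak_weights)), function(l)
    sum(lr$counts[w == l]), numeric(1))
  chi <- suppressWarnings(
    stats::chisq.test(obs, p = as.numeric(cfg$length_peak_weights)))
  expect_gt(chi$p.value, 0.01)
  # the two plant-typical peaks dominate
  names(obs) <- names(cfg$length_peak_weights)
  expect_true(all(obs[c("21", "24")] > obs[c("19", "26")]))
})

test_that("null simulation gives near-zero fold changes at depth", {
  cfg <- sim_config(n_hairpins = 4, n_families = 4, genome_length = 30000,
                    library_depth = 100000, nb_dispersion = 0, seed = 31)
  g <- generate_genome(cfg)
  libs <- simulate_libraries(g$refs, g$truth, cfg)
  anns <- lapply(libs, function(l) annotate_waterfall(length_filter(l), g$refs))
  fam <- family_profile_table(anns)
  ctrl <- grep("^rptm_control", names(fam))
  ws <- grep("^rptm_ws", names(fam))
  for (i in seq_len(nrow(fam))) {
    lfc <- log_fold_change(as.numeric(fam[i, ctrl]), as.numeric(fam[i, ws]))
    expect_lt(abs(lfc), 0.15)
  }
})

test_that("a +2 planted fold change is recovered on average", {
  # Monte-Carlo over independent simulation seeds; per-replicate noise from
  # nb_dispersion dominates depth, so the check is on the mean estimate
  ests <- vapply(1:8, function(s) {
    cfg <- sim_config(n_hairpins = 5, n_families = 5, genome_length = 30000,
                      library_depth = 100000,
                      condition_lfc = c(MIR101 = 2), seed = 300 + s)
    g <- generate_genome(cfg)
    libs <- simulate_libraries(g$refs, g$truth, cfg)
    anns <- lapply(libs, function(l)
      annotate_waterfall(length_filter(l), g$refs))
    fam <- family_profile_table(anns)
    i <- match("MIR101", fam$family_id)
    log_fold_change(
      as.numeric(fam[i, grep("^rptm_control", names(fam))]),
      as.numeric(fam[i, grep("^rptm_ws", names(fam))]))
  }, numeric(1))
  expect_lt(abs(mean(ests) - 2), 0.3)
})

test_that("fixtures round-trip through write and load byte-identically", {
  fx <- fixture_small()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture(fx$refs, fx$truth, fx$libs[1], d1, write_fastq = TRUE)
  write_fixture(fx$refs, fx$truth, fx$libs[1], d2, write_fastq = TRUE)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  lr <- fx$libs[[1]]
  back <- load_reads(file.path(d1, sprintf("reads_%s.fa.gz", lr$library_id)),
                     "fasta_collapsed")
  expect_identical(back$counts[order(names(back$counts))],
                   lr$counts[order(names(lr$counts))])
  fq <- load_reads(file.path(d1, sprintf("reads_%s.fastq.gz", lr$library_id)),
                   "fastq")
  expect_identical(fq$counts[order(names(fq$counts))],
                   lr$counts[order(names(lr$counts))])
  tr <- read.table(file.path(d1, "truth_hairpins.tsv"), sep = "\t",
                   header = TRUE)
  expect_equal(nrow(tr), fx$cfg$n_hairpins)
})
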