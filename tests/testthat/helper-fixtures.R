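# Shared simulated fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, build(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small two-condition study with planted fold changes and the catalog
# available to the waterfall
fixture_small <- function() memo("small", function() {
  cfg <- sim_config(n_hairpins = 8, n_families = 8, genome_length = 40000,
                    library_depth = 40000,
                    condition_lfc = c(MIR101 = 2, MIR102 = -2),
                    seed = 101)
  g <- generate_genome(cfg)
  libs <- simulate_libraries(g$refs, g$truth, cfg)
  anns <- lapply(libs, function(l) annotate_waterfall(length_filter(l), g$refs))
  list(cfg = cfg, refs = g$refs, truth = g$truth, libs = libs, anns = anns)
})

# discovery study: 10 hairpins, stars sequenced for 8 families only,
# catalog withheld so planted reads reach the genome tier
fixture_discovery <- function() memo("discovery", function() {
  fams <- sprintf("MIR%d", 101:110)
  sf <- setNames(c(rep(0.08, 8), 0, 0), fams)
  cfg <- sim_config(n_hairpins = 10, n_families = 10, genome_length = 60000,
                    library_depth = 50000, star_fraction = sf, seed = 11)
  g <- generate_genome(cfg)
  libs <- simulate_libraries(g$refs, g$truth, cfg)
  refs_nocat <- reference_set(genome = g$refs$genome,
                              structural_ncrna = g$refs$structural_ncrna,
                              repeats_mrna = g$refs$repeats_mrna)
  anns <- suppressWarnings(
    lapply(libs, function(l) annotate_waterfall(length_filter(l), refs_nocat)))
  list(cfg = cfg, refs = refs_nocat, truth = g$truth, libs = libs,
       anns = anns, star_families = fams[1:8])
})

# tiny hand-built reference set for unit tests
toy_refs <- function(mature = c("syn-miR900a" = "ACGTGTCAGTACGGATCCAAG"),
                     genome = NULL, ncrna = NULL, mrna = NULL) {
  set.seed(500)
  if (is.null(genome)) genome <- c(chr1 = random_dna(1, 2000))
  if (is.null(ncrna)) ncrna <- c(trna_1 = random_dna(1, 150))
  if (is.null(mrna)) mrna <- c(mrna_1 = random_dna(1, 300))
  reference_set(genome = genome, structural_ncrna = ncrna,
                repeats_mrna = mrna, mature_catalog = mature)
}
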