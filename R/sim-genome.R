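#' Reference set container
#'
#' Bundles the sequence references used by the annotation waterfall: the
#' genome, structural ncRNA decoys (rRNA/tRNA/snRNA/snoRNA role),
#' repeat/mRNA decoys (transposon + protein-coding role) and the mature
#' miRNA catalog. All sequences are normalized to uppercase DNA.
#'
#' @param genome named character vector of chromosome sequences.
#' @param structural_ncrna named character vector.
#' @param repeats_mrna named character vector.
#' @param mature_catalog named character vector, miRNA id -> mature
#'   sequence. Ids ending in \code{*} are treated as star strands.
#' @return object of class \code{reference_set}.
#' @export
reference_set <- function(genome = character(0),
                          structural_ncrna = character(0),
                          repeats_mrna = character(0),
                          mature_catalog = character(0)) {
  norm <- function(x, what) {
    if (length(x) == 0) return(setNames(character(0), character(0)))
    x <- setNames(normalize_seq(x), names(x))
    if (any(!nzchar(x))) stop(what, " contains empty sequences", call. = FALSE)
    assert_dna(x, what)
    x
  }
  structure(list(genome = norm(genome, "genome"),
                 structural_ncrna = norm(structural_ncrna, "structural_ncrna"),
                 repeats_mrna = norm(repeats_mrna, "repeats_mrna"),
                 mature_catalog = norm(mature_catalog, "mature_catalog")),
            class = "reference_set")
}

# bases that neither Watson-Crick nor G:T pair with `b`
non_pairing_bases <- function(b) {
  switch(b,
         A = c("A", "C", "G"),
         C = c("A", "C", "T"),
         G = c("A", "G"),
         T = c("C", "T"))
}

# Build one hairpin: mature on the 5' arm, star arm = reverse complement
# with `k` planted non-pairing mismatches, random loop, plus a tail so the
# star strand carries its own 3' overhang.
build_hairpin <- function(mature_len, k, loop_range, overhang) {
  mature <- random_dna(1, mature_len)
  arm2 <- strsplit(revcomp(mature), "", fixed = TRUE)[[1]]
  mbases <- strsplit(mature, "", fixed = TRUE)[[1]]
  if (k > 0) {
    # keep duplex ends paired so star coordinates stay well-defined
    pos <- sample(seq(4, mature_len - overhang - 3), k)
    for (i in pos) {
      j <- mature_len - i + 1
      arm2[j] <- sample(non_pairing_bases(mbases[i]), 1)
    }
  }
  loop <- random_dna(1, sample(seq(loop_range[1], loop_range[2]), 1))
  tail <- random_dna(1, overhang)
  star <- paste0(paste(arm2[(overhang + 1):mature_len], collapse = ""), tail)
  precursor <- paste0(mature, loop, paste(arm2, collapse = ""), tail)
  list(mature = mature, star = star, precursor = precursor,
       loop_len = nchar(loop))
}

count_occurrences <- function(pattern, subjects) {
  if (length(subjects) == 0) return(0L)
  fwd <- sum(vapply(subjects, function(s)
    length(gregexpr(pattern, s, fixed = TRUE)[[1]]) *
      (regexpr(pattern, s, fixed = TRUE) > 0), integer(1)))
  rev <- sum(vapply(subjects, function(s)
    length(gregexpr(revcomp(pattern), s, fixed = TRUE)[[1]]) *
      (regexpr(revcomp(pattern), s, fixed = TRUE) > 0), integer(1)))
  fwd + rev
}

#' Generate the toy genome with planted hairpins and decoys
#'
#' Creates a single-chromosome genome in which \code{n_hairpins} miRNA
#' precursors are embedded at non-overlapping loci, together with decoy
#' structural-ncRNA and repeat/mRNA reference sequences and the mature
#' catalog (mature and star strands) for the planted families. The ground
#' truth records each precursor, its mature/star sequences and locus, the
#' per-family true log2 fold changes and the expected per-library miRNA
#' read counts.
#'
#' Each planted mature:star duplex carries at most
#' \code{config$planted_mismatches} mismatches and a 3' overhang of
#' \code{config$star_overhang} nt on each strand, so every planted hairpin
#' satisfies the novel-miRNA caller's own duplex criteria. Every planted
#' mature sequence occurs exactly once in the genome (either strand) and in
#' none of the decoys.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with elements \code{refs} (a \code{\link{reference_set}})
#'   and \code{truth} (class \code{sim_truth}: \code{planted_hairpins}
#'   data frame with 0-based half-open loci, \code{true_lfc},
#'   \code{expected_counts} matrix, \code{library_info} data frame).
#' @export
generate_genome <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  L <- config$mature_length
  n <- config$n_hairpins

  # worst-case precursor length: 2 arms + max loop + overhang tail
  prec_max <- 2L * L + config$loop_range[2] + config$star_overhang
  slot <- prec_max + 20L
  if (n > 0 && n * slot > config$genome_length)
    stop(sprintf(paste0("genome_length %d too small to place %d hairpins ",
                        "(need >= %d)"), config$genome_length, n, n * slot),
         call. = FALSE)

  ncrna <- setNames(
    random_dna(config$n_decoy_ncrna,
               sample(seq(config$decoy_length_range[1],
                          config$decoy_length_range[2]),
                      config$n_decoy_ncrna, replace = TRUE)),
    if (config$n_decoy_ncrna > 0)
      sprintf("ncrna_%02d", seq_len(config$n_decoy_ncrna)) else character(0))
  mrna <- setNames(
    random_dna(config$n_decoy_mrna,
               sample(seq(config$decoy_length_range[1],
                          config$decoy_length_range[2]),
                      config$n_decoy_mrna, replace = TRUE)),
    if (config$n_decoy_mrna > 0)
      sprintf("mrna_%02d", seq_len(config$n_decoy_mrna)) else character(0))

  genome <- random_dna(1, config$genome_length)

  fams <- sim_family_ids(config$n_families)
  hp <- NULL
  if (n > 0) {
    fam_of_hp <- fams[(seq_len(n) - 1L) %% config$n_families + 1L]
    member_idx <- stats::ave(seq_len(n), fam_of_hp, FUN = seq_along)
    mirna_ids <- sprintf("syn-miR%s%s", sub("^MIR", "", fam_of_hp),
                         letters[member_idx])
    # equally spaced blocks, random offset inside each block
    block <- config$genome_length %/% n
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in 1:50) {
        h <- build_hairpin(L, config$planted_mismatches,
                           config$loop_range, config$star_overhang)
        plen <- nchar(h$precursor)
        start <- (i - 1L) * block + sample.int(block - plen - 1L, 1)
        cand <- paste0(substr(genome, 1, start),
                       h$precursor,
                       substr(genome, start + plen + 1, config$genome_length))
        others <- c(ncrna, mrna,
                    if (i > 1) vapply(rows[seq_len(i - 1)],
                                      `[[`, character(1), "mature"))
        if (count_occurrences(h$mature, cand) == 1 &&
            count_occurrences(h$mature, c(ncrna, mrna)) == 0 &&
            !any(vapply(others, function(o)
              grepl(h$mature, o, fixed = TRUE), logical(1)))) {
          genome <- cand
          rows[[i]] <- list(
            family_id = fam_of_hp[i], mirna_id = mirna_ids[i],
            star_id = paste0(mirna_ids[i], "*"), chrom = "chr1",
            mature_start = start, mature_end = start + L,
            strand = "+",
            precursor_start = start, precursor_end = start + plen,
            precursor = h$precursor, mature = h$mature, star = h$star,
            arm = "5p")
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("failed to place a unique hairpin; genome too repetitive",
                    call. = FALSE)
    }
    hp <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  } else {
    hp <- data.frame(family_id = character(0), mirna_id = character(0),
                     star_id = character(0), chrom = character(0),
                     mature_start = integer(0), mature_end = integer(0),
                     strand = character(0), precursor_start = integer(0),
                     precursor_end = integer(0), precursor = character(0),
                     mature = character(0), star = character(0),
                     arm = character(0), stringsAsFactors = FALSE)
  }

  catalog <- character(0)
  if (n > 0) {
    catalog <- setNames(c(hp$mature, hp$star), c(hp$mirna_id, hp$star_id))
  }

  refs <- reference_set(genome = c(chr1 = genome),
                        structural_ncrna = ncrna,
                        repeats_mrna = mrna,
                        mature_catalog = catalog)

  true_lfc <- setNames(rep(0, config$n_families), fams)
  common <- intersect(names(config$condition_lfc), fams)
  true_lfc[common] <- config$condition_lfc[common]

  lib_info <- expand.grid(replicate = seq_len(config$replicates_per_condition),
                          condition = c("control", "water_stress"),
                          stringsAsFactors = FALSE)[, c("condition", "replicate")]
  lib_info$library_id <- sprintf("%s_%d",
                                 ifelse(lib_info$condition == "control",
                                        "control", "ws"),
                                 lib_info$replicate)

  # expected mature+star count per family per library (NB means)
  w <- if (config$n_families > 0) rep(1 / config$n_families, config$n_families)
       else numeric(0)
  expected <- matrix(0, nrow = config$n_families, ncol = nrow(lib_info),
                     dimnames = list(fams, lib_info$library_id))
  for (j in seq_len(nrow(lib_info))) {
    scale <- if (lib_info$condition[j] == "water_stress") 2^true_lfc
             else rep(1, length(true_lfc))
    if (config$n_families > 0)
      expected[, j] <- config$library_depth * config$mirna_fraction * w * scale
  }

  truth <- structure(list(planted_hairpins = hp,
                          true_lfc = true_lfc,
                          expected_counts = expected,
                          library_info = lib_info,
                          config_seed = config$seed),
                     class = "sim_truth")
  list(refs = refs, truth = truth)
}
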