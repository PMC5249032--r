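#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic small-RNA study:
#' a toy genome carrying planted miRNA hairpins and decoy features, and
#' replicated two-condition libraries with known fold-change effects.
#'
#' Planted hairpins are assigned round-robin to \code{n_families} families.
#' Water-stress libraries scale each family's expected mature-read count by
#' \code{2^condition_lfc[family]}; families absent from \code{condition_lfc}
#' have a true log2 fold change of 0.
#'
#' @param n_hairpins number of planted miRNA hairpin loci.
#' @param n_decoy_ncrna number of structural-ncRNA decoy sequences
#'   (rRNA/tRNA/snRNA/snoRNA stand-ins).
#' @param n_decoy_mrna number of transposon/mRNA decoy sequences (these also
#'   serve as the transcript set for target prediction).
#' @param genome_length toy genome length in nt (single chromosome).
#' @param mature_length mature miRNA length in nt, within 18..28 (default 21).
#' @param star_overhang length of the 3' overhang on each duplex strand
#'   (default 2 nt, the canonical Dicer signature).
#' @param n_families number of miRNA families (<= n_hairpins when hairpins
#'   are planted).
#' @param condition_lfc named numeric vector, family id -> true log2 fold
#'   change (water stress vs control).
#' @param replicates_per_condition replicate libraries per condition.
#' @param library_depth total reads per library.
#' @param nb_dispersion negative-binomial dispersion of replicate counts
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson noise.
#' @param length_peak_weights named numeric vector of read-length
#'   probabilities for background reads; names are lengths in nt. The
#'   default has the two peaks at 21 and 24 nt typical of plant small-RNA
#'   populations.
#' @param mirna_fraction expected fraction of a library drawn from planted
#'   mature/star miRNA reads.
#' @param star_fraction fraction of a family's miRNA reads emitted as the
#'   star strand; either a scalar or a named per-family vector.
#' @param background_decoy_fraction fraction of background reads sampled
#'   from decoy features (the remainder is sampled uniformly from the
#'   genome).
#' @param planted_mismatches number of mismatches planted in each
#'   mature:star duplex (0..2).
#' @param decoy_length_range length range (nt) for decoy features.
#' @param loop_range hairpin loop length range in nt.
#' @param seed integer seed controlling all simulation randomness.
#' @return an object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_hairpins = 10,
                       n_decoy_ncrna = 5,
                       n_decoy_mrna = 5,
                       genome_length = 50000,
                       mature_length = 21,
                       star_overhang = 2,
                       n_families = n_hairpins,
                       condition_lfc = numeric(0),
                       replicates_per_condition = 2,
                       library_depth = 100000,
                       nb_dispersion = 0.1,
                       length_peak_weights = NULL,
                       mirna_fraction = 0.35,
                       star_fraction = 0.05,
                       background_decoy_fraction = 0.7,
                       planted_mismatches = 2,
                       decoy_length_range = c(120, 400),
                       loop_range = c(8, 15),
                       seed = 1L) {
  if (is.null(length_peak_weights)) {
    # bimodal plant-like profile over 18..28 nt with peaks at 21 and 24
    length_peak_weights <- c(
      `18` = 0.04, `19` = 0.05, `20` = 0.08, `21` = 0.28, `22` = 0.08,
      `23` = 0.08, `24` = 0.22, `25` = 0.07, `26` = 0.04, `27` = 0.03,
      `28` = 0.03)
  }
  cfg <- list(
    n_hairpins = as.integer(n_hairpins),
    n_decoy_ncrna = as.integer(n_decoy_ncrna),
    n_decoy_mrna = as.integer(n_decoy_mrna),
    genome_length = as.integer(genome_length),
    mature_length = as.integer(mature_length),
    star_overhang = as.integer(star_overhang),
    n_families = as.integer(n_families),
    condition_lfc = condition_lfc,
    replicates_per_condition = as.integer(replicates_per_condition),
    library_depth = as.integer(library_depth),
    nb_dispersion = nb_dispersion,
    length_peak_weights = length_peak_weights,
    mirna_fraction = mirna_fraction,
    star_fraction = star_fraction,
    background_decoy_fraction = background_decoy_fraction,
    planted_mismatches = as.integer(planted_mismatches),
    decoy_length_range = as.integer(decoy_length_range),
    loop_range = as.integer(loop_range),
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  w <- cfg$length_peak_weights
  if (abs(sum(w) - 1) > 1e-8)
    stop("length_peak_weights must sum to 1", call. = FALSE)
  if (is.null(names(w)) || anyNA(as.integer(names(w))))
    stop("length_peak_weights must be named by read length", call. = FALSE)
  if (cfg$library_depth <= 0) stop("library_depth must be > 0", call. = FALSE)
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be >= 0", call. = FALSE)
  if (cfg$mature_length < 18 || cfg$mature_length > 28)
    stop("mature_length must lie within [18, 28]", call. = FALSE)
  if (cfg$n_hairpins > 0 && cfg$n_families > cfg$n_hairpins)
    stop("n_families cannot exceed n_hairpins", call. = FALSE)
  if (cfg$mirna_fraction < 0 || cfg$mirna_fraction >= 1)
    stop("mirna_fraction must lie in [0, 1)", call. = FALSE)
  if (cfg$planted_mismatches < 0 || cfg$planted_mismatches > 2)
    stop("planted_mismatches must be 0, 1 or 2", call. = FALSE)
  cfg
}

# family ids MIR101, MIR102, ... and member ids syn-miR101a-5p etc.
sim_family_ids <- function(n) sprintf("MIR%d", 100 + seq_len(n))
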