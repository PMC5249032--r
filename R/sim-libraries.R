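#' Collapsed small-RNA library container
#'
#' One sequencing library as a collapsed map sequence -> count plus library
#' metadata. Sequences are uppercase DNA; counts are positive integers.
#'
#' @param library_id library identifier.
#' @param condition \code{"control"} or \code{"water_stress"}.
#' @param replicate replicate index (1-based).
#' @param counts named integer vector; names are read sequences.
#' @return object of class \code{library_reads}.
#' @export
library_reads <- function(library_id, condition, replicate, counts) {
  condition <- match.arg(condition, c("control", "water_stress"))
  if (length(counts)) {
    seqs <- normalize_seq(names(counts))
    assert_dna(seqs, "reads")
    cnt <- as.integer(counts)
    if (any(cnt < 1)) stop("counts must be >= 1", call. = FALSE)
    if (anyDuplicated(seqs)) {
      cnt <- as.integer(rowsum(cnt, seqs)[, 1])
      seqs <- sort(unique(seqs))
      # rowsum sorts by group; keep names aligned
      counts <- setNames(cnt, seqs)
    } else counts <- setNames(cnt, seqs)
  } else counts <- setNames(integer(0), character(0))
  structure(list(library_id = library_id, condition = condition,
                 replicate = as.integer(replicate), counts = counts),
            class = "library_reads")
}

#' @export
print.library_reads <- function(x, ...) {
  cat(sprintf("library_reads '%s' (%s, rep %d): %d unique / %d total reads\n",
              x$library_id, x$condition, x$replicate,
              length(x$counts), sum(x$counts)))
  invisible(x)
}

#' Total and unique read counts of a library
#' @param lr a \code{library_reads}.
#' @return named numeric vector with elements \code{total} and \code{unique}.
#' @export
library_size <- function(lr) {
  c(total = sum(lr$counts), unique = length(lr$counts))
}

# draw one NB count; dispersion 0 degrades to Poisson
rnb1 <- function(n, mu, dispersion) {
  if (dispersion <= 0) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate replicated two-condition small-RNA libraries
#'
#' Draws per-hairpin miRNA read counts negative-binomially around the
#' expected means recorded in the truth (water-stress means scaled by the
#' per-family fold changes), emits star-strand reads as a configured
#' fraction of each family's miRNA reads, and fills the remainder of each
#' library with background reads sampled from the decoy features and from
#' uniform genome positions with the configured read-length distribution.
#' Each library contains exactly \code{config$library_depth} reads.
#'
#' @param refs \code{reference_set} from \code{\link{generate_genome}}.
#' @param truth \code{sim_truth} from \code{\link{generate_genome}}.
#' @param config the same \code{\link{sim_config}}.
#' @return list of \code{\link{library_reads}}, one per replicate per
#'   condition, named by library id.
#' @export
simulate_libraries <- function(refs, truth, config) {
  validate_sim_config(config)
  if (!inherits(truth, "sim_truth") || truth$config_seed != config$seed)
    stop("truth must come from generate_genome() with the same config",
         call. = FALSE)
  hp <- truth$planted_hairpins
  info <- truth$library_info
  fams <- rownames(truth$expected_counts)
  starfrac <- config$star_fraction
  if (length(starfrac) == 1 && is.null(names(starfrac)))
    starfrac <- setNames(rep(starfrac, length(fams)), fams)

  genome <- refs$genome[[1]]
  glen <- nchar(genome)
  decoys <- c(refs$structural_ncrna, refs$repeats_mrna)
  lens <- as.integer(names(config$length_peak_weights))
  lenp <- as.numeric(config$length_peak_weights)

  out <- vector("list", nrow(info))
  names(out) <- info$library_id
  for (j in seq_len(nrow(info))) {
    set.seed(config$seed + 1000L + j)
    seqs <- character(0); cnts <- integer(0)

    n_mirna_total <- 0L
    if (nrow(hp) > 0) {
      members_per_fam <- table(hp$family_id)
      for (i in seq_len(nrow(hp))) {
        fam <- hp$family_id[i]
        mu <- truth$expected_counts[fam, info$library_id[j]] /
          members_per_fam[[fam]]
        n_i <- rnb1(1, mu, config$nb_dispersion)
        sf <- if (fam %in% names(starfrac)) starfrac[[fam]] else 0
        n_star <- if (n_i > 0 && sf > 0) rbinom(1, n_i, sf) else 0L
        n_mat <- n_i - n_star
        if (n_mat > 0) { seqs <- c(seqs, hp$mature[i]); cnts <- c(cnts, n_mat) }
        if (n_star > 0) { seqs <- c(seqs, hp$star[i]); cnts <- c(cnts, n_star) }
        n_mirna_total <- n_mirna_total + n_i
      }
    }
    n_bg <- config$library_depth - n_mirna_total
    if (n_bg < 0)
      stop("miRNA reads exceed library_depth; lower mirna_fraction",
           call. = FALSE)
    if (n_bg > 0) {
      n_dec <- if (length(decoys)) rbinom(1, n_bg, config$background_decoy_fraction)
               else 0L
      n_gen <- n_bg - n_dec
      bg <- character(0)
      if (n_dec > 0) {
        dl <- nchar(decoys)
        which_d <- sample.int(length(decoys), n_dec, replace = TRUE,
                              prob = dl / sum(dl))
        rl <- sample(lens, n_dec, replace = TRUE, prob = lenp)
        rl <- pmin(rl, dl[which_d])
        st <- floor(runif(n_dec) * (dl[which_d] - rl + 1)) + 1L
        bg <- c(bg, substring(decoys[which_d], st, st + rl - 1L))
      }
      if (n_gen > 0) {
        # background emulates non-miRNA genomic small RNAs: positions
        # overlapping a planted precursor are rejected and resampled so
        # the planted truth stays uncontaminated
        rl <- sample(lens, n_gen, replace = TRUE, prob = lenp)
        st <- integer(n_gen)
        todo <- seq_len(n_gen)
        while (length(todo)) {
          st[todo] <- floor(runif(length(todo)) * (glen - rl[todo] + 1)) + 1L
          if (nrow(hp)) {
            bad <- (outer(st[todo], hp$precursor_end, "<=") &
                    outer(st[todo] + rl[todo] - 1L, hp$precursor_start, ">"))
            todo <- todo[rowSums(bad) > 0]
          } else todo <- integer(0)
        }
        minus <- runif(n_gen) < 0.5
        s <- character(n_gen)
        s[!minus] <- substring(genome, st[!minus], st[!minus] + rl[!minus] - 1L)
        s[minus] <- revcomp(substring(genome, st[minus], st[minus] + rl[minus] - 1L))
        bg <- c(bg, s)
      }
      tb <- table(bg)
      seqs <- c(seqs, names(tb)); cnts <- c(cnts, as.integer(tb))
    }
    out[[j]] <- library_reads(info$library_id[j], info$condition[j],
                              info$replicate[j], setNames(cnts, seqs))
  }
  out
}
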