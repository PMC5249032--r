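#' Run the full small-RNA analysis pipeline
#'
#' Annotates each library through the waterfall, writes the tally table,
#' per-miRNA and per-family abundance profiles with tiers, the star
#' summary, family-level differential-expression results and the novel
#' miRNA calls, each as a TSV under \code{out_dir}. All outputs are
#' deterministic functions of the inputs.
#'
#' @param libraries list of \code{\link{library_reads}}.
#' @param refs a \code{\link{reference_set}}.
#' @param out_dir output directory (created if absent); NULL skips
#'   writing.
#' @param min_len,max_len length-filter bounds.
#' @param mirbase_max_mismatch catalog-tier mismatch tolerance.
#' @param denominator RPTM denominator mode (\code{"filtered"} or
#'   \code{"genome"}).
#' @param lfc_min,fdr_max differential-expression call thresholds.
#' @param discovery_args list of extra arguments for
#'   \code{\link{discover_novel}} (e.g. \code{min_count}); set to NULL to
#'   skip novel discovery.
#' @return list with elements \code{annotations}, \code{tally},
#'   \code{mirna_profiles}, \code{family_profiles}, \code{stars},
#'   \code{de}, \code{novel}, \code{paths}.
#' @export
run_pipeline <- function(libraries, refs, out_dir = NULL,
                         min_len = 18L, max_len = 28L,
                         mirbase_max_mismatch = 2L,
                         denominator = c("filtered", "genome"),
                         lfc_min = 1.0, fdr_max = 0.05,
                         discovery_args = list()) {
  denominator <- match.arg(denominator)
  anns <- lapply(libraries, function(lr)
    annotate_waterfall(length_filter(lr, min_len, max_len), refs,
                       mirbase_max_mismatch = mirbase_max_mismatch))
  tally <- tally_table(anns)
  denos <- library_denominators(anns, mode = denominator)
  prof <- mirna_profile_table(anns, denos)
  fam <- family_profile_table(anns, denos)
  stars <- star_summary(prof)

  lib_ids <- vapply(anns, `[[`, character(1), "library_id")
  conds <- vapply(anns, `[[`, character(1), "condition")
  de <- NULL
  if (length(unique(conds)) == 2 && nrow(fam) > 0) {
    raw_cols <- paste0("raw_", lib_ids)
    cmat <- as.matrix(fam[, raw_cols, drop = FALSE])
    rownames(cmat) <- fam$family_id
    colnames(cmat) <- lib_ids
    de <- de_test(cmat, conds, lib_sizes = denos[lib_ids],
                  lfc_min = lfc_min, fdr_max = fdr_max)
  }

  novel <- NULL
  if (!is.null(discovery_args)) {
    disc <- do.call(discover_novel,
                    c(list(anns = anns, refs = refs, libraries = libraries),
                      discovery_args))
    novel <- disc$novel
  }

  paths <- character(0)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir))
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wtsv <- function(df, name) {
      f <- file.path(out_dir, name)
      write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                  f, sep = "\t", quote = FALSE, row.names = FALSE)
      f
    }
    paths["tally"] <- wtsv(tally, "tally.tsv")
    paths["mirna_profiles"] <- wtsv(prof, "mirna_profiles.tsv")
    paths["family_profiles"] <- wtsv(fam, "family_profiles.tsv")
    paths["stars"] <- wtsv(stars, "star_summary.tsv")
    if (!is.null(de)) paths["de"] <- wtsv(de, "de_families.tsv")
    if (!is.null(novel)) paths["novel"] <- wtsv(novel, "novel_mirnas.tsv")
  }
  invisible(list(annotations = anns, tally = tally, mirna_profiles = prof,
                 family_profiles = fam, stars = stars, de = de, novel = novel,
                 paths = paths))
}
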