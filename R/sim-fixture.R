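#' Write a simulated study to disk
#'
#' Serializes the reference set, libraries and ground truth under one
#' directory: references as FASTA, libraries as gzipped collapsed FASTA
#' (headers \code{<lib>_seq<N>_x<COUNT>}) and optionally as FASTQ
#' (Phred+33, constant quality, one record per read occurrence), and truth
#' tables as TSV.
#'
#' @param refs \code{reference_set}.
#' @param truth \code{sim_truth}.
#' @param libraries list of \code{library_reads}.
#' @param out_dir output directory (created if absent).
#' @param write_fastq also write expanded FASTQ files (large for deep
#'   libraries; default TRUE).
#' @return named character vector of written paths, invisibly.
#' @export
write_fixture <- function(refs, truth, libraries, out_dir,
                          write_fastq = TRUE) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir, call. = FALSE)
  paths <- character(0)
  wfa <- function(x, file) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), file)
    file
  }
  paths["genome"] <- wfa(refs$genome, file.path(out_dir, "genome.fa"))
  paths["structural_ncrna"] <- wfa(refs$structural_ncrna,
                                   file.path(out_dir, "structural_ncrna.fa"))
  paths["repeats_mrna"] <- wfa(refs$repeats_mrna,
                               file.path(out_dir, "repeats_mrna.fa"))
  paths["mature_catalog"] <- wfa(refs$mature_catalog,
                                 file.path(out_dir, "mature_catalog.fa"))

  for (lr in libraries) {
    fa <- file.path(out_dir, sprintf("reads_%s.fa.gz", lr$library_id))
    ids <- sprintf("%s_seq%d_x%d", lr$library_id, seq_along(lr$counts),
                   as.integer(lr$counts))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(setNames(names(lr$counts), ids)),
      fa, compress = TRUE)
    paths[paste0("reads_", lr$library_id)] <- fa
    if (write_fastq) {
      fq <- file.path(out_dir, sprintf("reads_%s.fastq.gz", lr$library_id))
      expanded <- rep(names(lr$counts), lr$counts)
      qd <- Biostrings::DNAStringSet(expanded)
      names(qd) <- sprintf("%s_read%d", lr$library_id, seq_along(expanded))
      Biostrings::writeXStringSet(
        qd, fq, compress = TRUE, format = "fastq",
        qualities = Biostrings::BStringSet(
          vapply(nchar(expanded),
                 function(n) paste(rep("I", n), collapse = ""), character(1))))
      paths[paste0("fastq_", lr$library_id)] <- fq
    }
  }

  wtsv <- function(df, file) {
    write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    file
  }
  paths["hairpins"] <- wtsv(truth$planted_hairpins,
                            file.path(out_dir, "truth_hairpins.tsv"))
  paths["true_lfc"] <- wtsv(
    data.frame(family_id = names(truth$true_lfc), lfc = truth$true_lfc,
               row.names = NULL),
    file.path(out_dir, "truth_lfc.tsv"))
  ec <- as.data.frame(truth$expected_counts)
  ec <- cbind(family_id = rownames(truth$expected_counts), ec)
  paths["expected_counts"] <- wtsv(ec,
                                   file.path(out_dir, "truth_expected_counts.tsv"))
  paths["libraries"] <- wtsv(truth$library_info,
                             file.path(out_dir, "libraries.tsv"))
  invisible(paths)
}
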