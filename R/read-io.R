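#' Load and collapse small-RNA reads
#'
#' Reads a library from FASTA or FASTQ. In \code{fasta_collapsed} format
#' the count of each unique read is encoded in the header as a trailing
#' \code{_x<COUNT>} (e.g. \code{seq1_x35}); in \code{fasta_raw} and
#' \code{fastq} each record counts once. Identical sequences are merged
#' with summed counts; sequences are case-folded to uppercase and RNA U is
#' converted to DNA T. Gzipped files are handled transparently.
#'
#' @param path input file.
#' @param format one of \code{"fasta_collapsed"}, \code{"fastq"},
#'   \code{"fasta_raw"}.
#' @param library_id library identifier (default: file base name).
#' @param condition,replicate library metadata.
#' @return a \code{\link{library_reads}}.
#' @export
load_reads <- function(path,
                       format = c("fasta_collapsed", "fastq", "fasta_raw"),
                       library_id = NULL, condition = "control",
                       replicate = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(library_id))
    library_id <- sub("\\.(fa|fasta|fq|fastq)(\\.gz)?$", "", basename(path))
  fmt <- if (format == "fastq") "fastq" else "fasta"
  recs <- tryCatch(
    Biostrings::readBStringSet(path, format = fmt),
    error = function(e) stop("malformed ", fmt, " file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (length(recs) == 0) {
    warning("empty read file: ", path, call. = FALSE)
    return(library_reads(library_id, condition, replicate,
                         setNames(integer(0), character(0))))
  }
  seqs <- normalize_seq(as.character(recs))
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad))
    stop(sprintf("malformed record %d in '%s': non-ACGTU sequence",
                 which(bad)[1], path), call. = FALSE)
  counts <- if (format == "fasta_collapsed") {
    m <- regmatches(names(recs), regexpr("_x(\\d+)$", names(recs)))
    if (length(m) != length(recs)) {
      idx <- which(!grepl("_x\\d+$", names(recs)))[1]
      stop(sprintf(paste0("malformed record %d in '%s': header '%s' lacks ",
                          "the _x<COUNT> suffix"),
                   idx, path, names(recs)[idx]), call. = FALSE)
    }
    as.integer(sub("^_x", "", m))
  } else rep(1L, length(recs))
  agg <- rowsum(counts, seqs)
  library_reads(library_id, condition, replicate,
                setNames(as.integer(agg[, 1]), rownames(agg)))
}

#' Read a FASTA reference into a named character vector
#'
#' @param path FASTA file (optionally gzipped).
#' @return named character vector of uppercase DNA sequences.
#' @export
load_fasta <- function(path) {
  recs <- Biostrings::readBStringSet(path)
  setNames(normalize_seq(as.character(recs)), names(recs))
}

#' Load a serialized reference set from a fixture directory
#'
#' Expects the file layout written by \code{\link{write_fixture}}.
#'
#' @param dir directory containing \code{genome.fa},
#'   \code{structural_ncrna.fa}, \code{repeats_mrna.fa},
#'   \code{mature_catalog.fa}.
#' @return a \code{\link{reference_set}}.
#' @export
load_reference_set <- function(dir) {
  reference_set(genome = load_fasta(file.path(dir, "genome.fa")),
                structural_ncrna = load_fasta(file.path(dir, "structural_ncrna.fa")),
                repeats_mrna = load_fasta(file.path(dir, "repeats_mrna.fa")),
                mature_catalog = load_fasta(file.path(dir, "mature_catalog.fa")))
}

#' Apply the small-RNA length filter
#'
#' Retains reads whose length lies within \code{[min_len, max_len]}
#' (defaults 18 and 28 nt, both inclusive) and records the removed read
#' mass in the \code{removed} attribute (total and unique counts).
#'
#' @param reads a \code{\link{library_reads}}.
#' @param min_len,max_len inclusive length bounds in nt.
#' @return filtered \code{library_reads} with a \code{removed} attribute.
#' @export
length_filter <- function(reads, min_len = 18L, max_len = 28L) {
  if (min_len > max_len)
    stop("min_len must not exceed max_len", call. = FALSE)
  w <- nchar(names(reads$counts))
  keep <- w >= min_len & w <= max_len
  out <- library_reads(reads$library_id, reads$condition, reads$replicate,
                       reads$counts[keep])
  attr(out, "removed") <- c(total = sum(reads$counts[!keep]),
                            unique = sum(!keep))
  out
}
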