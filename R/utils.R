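#' @useDynLib mirpipe, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optimize p.adjust phyper rbinom rmultinom rnbinom rpois runif setNames
#' @importFrom utils write.table read.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Reverse complement of DNA strings
#'
#' Vectorized reverse complement over the uppercase DNA alphabet.
#'
#' @param x character vector of DNA sequences (A/C/G/T).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) > 100)
    return(as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(x))))
  out <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(out, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

#' Generate random DNA sequences
#'
#' @param n number of sequences.
#' @param len length (recycled).
#' @return character vector of uppercase DNA.
#' @export
random_dna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(len, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    character(1))
}

# normalize raw sequence input: uppercase, RNA U -> DNA T
normalize_seq <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))

assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad))
    stop(sprintf("%s contains non-ACGT characters (first offender: '%s')",
                 what, x[which(bad)[1]]), call. = FALSE)
  invisible(x)
}

# split sequences into a character matrix (rows = sequences), all same width
seq_char_matrix <- function(x) {
  w <- nchar(x[1])
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         ncol = w, byrow = TRUE)
}

# TRUE where bases a:b form a Watson-Crick pair, optionally G:T wobble
is_pair <- function(a, b, gu = TRUE) {
  wc <- (a == "A" & b == "T") | (a == "T" & b == "A") |
        (a == "C" & b == "G") | (a == "G" & b == "C")
  if (gu) wc | (a == "G" & b == "T") | (a == "T" & b == "G") else wc
}
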