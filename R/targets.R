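#' Predict miRNA target sites by bounded-mismatch complementarity
#'
#' Slides the reverse complement of the miRNA along each transcript
#' (substitution-only, no indels or bulges) and scores each offset:
#' Watson-Crick pairs count 0, G:U wobbles count \code{wobble_weight}
#' (default 0.5) and other positions count 1. Sites with score at most
#' \code{max_mismatch} are reported, best site per transcript first.
#'
#' @param mirna named character vector of mature miRNA sequences (18-28
#'   nt; U is converted to T).
#' @param transcripts named character vector of sense transcript
#'   sequences.
#' @param max_mismatch maximum mismatch score of a retained site
#'   (default 3, i.e. "fewer than 4 mismatches").
#' @param wobble_weight mismatch contribution of a G:U pair: 0, 0.5 or 1.
#' @return data frame: mirna_id, transcript_id, position (0-based site
#'   start on the transcript), mismatches (non-pairing positions), wobbles,
#'   score.
#' @export
predict_targets <- function(mirna, transcripts, max_mismatch = 3,
                            wobble_weight = 0.5) {
  if (!length(transcripts)) stop("transcripts must be non-empty", call. = FALSE)
  if (is.null(names(mirna)))
    names(mirna) <- sprintf("mirna_%d", seq_along(mirna))
  mirna <- normalize_seq(mirna)
  transcripts <- normalize_seq(transcripts)
  bad <- nchar(mirna) < 18 | nchar(mirna) > 28
  if (any(bad))
    stop("miRNA length outside 18-28 nt: ", names(mirna)[bad][1],
         call. = FALSE)
  rows <- list()
  for (mi in seq_along(mirna)) {
    m <- mirna[[mi]]
    w <- nchar(m)
    rc <- strsplit(revcomp(m), "", fixed = TRUE)[[1]]
    for (ti in seq_along(transcripts)) {
      tseq <- strsplit(transcripts[[ti]], "", fixed = TRUE)[[1]]
      L <- length(tseq)
      if (L < w) next
      n_off <- L - w + 1L
      mismatch <- integer(n_off)
      wobble <- integer(n_off)
      for (j in seq_len(w)) {
        tb <- tseq[j:(j + n_off - 1L)]
        wc <- tb == rc[j]
        # miRNA base = complement(rc[j]); G:U wobble means miRNA G with
        # target T (rc = C) or miRNA T with target G (rc = A)
        wb <- (rc[j] == "C" & tb == "T") | (rc[j] == "A" & tb == "G")
        mismatch <- mismatch + as.integer(!wc & !wb)
        wobble <- wobble + as.integer(wb)
      }
      score <- mismatch + wobble_weight * wobble
      keep <- which(score <= max_mismatch)
      if (length(keep))
        rows[[length(rows) + 1L]] <- data.frame(
          mirna_id = names(mirna)[mi],
          transcript_id = names(transcripts)[ti],
          position = keep - 1L,
          mismatches = mismatch[keep],
          wobbles = wobble[keep],
          score = score[keep],
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(mirna_id = character(0), transcript_id = character(0),
                      position = integer(0), mismatches = integer(0),
                      wobbles = integer(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$mirna_id, out$transcript_id, out$score, out$position), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hypergeometric over-representation test of annotation terms
#'
#' One-sided hypergeometric test of each annotation term for
#' over-representation in a target gene set against a gene universe, with
#' BH-FDR across terms.
#'
#' @param target_genes character vector of target gene ids (subset of the
#'   universe).
#' @param annotation data frame with columns \code{gene}, \code{term} and
#'   optionally \code{term_name}.
#' @param universe character vector of all gene ids.
#' @return data frame sorted by p-value: term_id, term_name, k_targets,
#'   K_universe, n_set, N_universe, pvalue, fdr.
#' @export
hypergeom_enrichment <- function(target_genes, annotation, universe) {
  if (!length(universe)) stop("universe must be non-empty", call. = FALSE)
  universe <- unique(universe)
  target_genes <- unique(target_genes)
  if (!all(target_genes %in% universe))
    stop("target_genes must be a subset of the universe", call. = FALSE)
  annotation <- annotation[annotation$gene %in% universe, , drop = FALSE]
  if (is.null(annotation$term_name)) annotation$term_name <- annotation$term
  N <- length(universe)
  n <- length(target_genes)
  terms <- unique(annotation[, c("term", "term_name")])
  K <- vapply(terms$term, function(tm)
    length(unique(annotation$gene[annotation$term == tm])), integer(1))
  k <- vapply(terms$term, function(tm)
    sum(unique(annotation$gene[annotation$term == tm]) %in% target_genes),
    integer(1))
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term_id = terms$term, term_name = terms$term_name,
                    k_targets = k, K_universe = K, n_set = n, N_universe = N,
                    pvalue = p, fdr = bh_fdr(p),
                    stringsAsFactors = FALSE)
  out <- out[order(out$pvalue, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
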