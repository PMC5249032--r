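# Exact-substring matching of many short reads against a set of reference
# sequences, on one or both strands. Reads are grouped by width and matched
# with a Biostrings PDict, the standard indexed engine for constant-width
# dictionaries.
substring_hits <- function(reads, subjects, both_strands = TRUE) {
  hits <- logical(length(reads))
  if (length(reads) == 0 || length(subjects) == 0) return(hits)
  subj <- Biostrings::DNAStringSet(subjects)
  subj_all <- if (both_strands) c(subj, Biostrings::reverseComplement(subj))
              else subj
  widths <- nchar(reads)
  for (w in unique(widths)) {
    idx <- which(widths == w)
    usable <- Biostrings::width(subj_all) >= w
    if (!any(usable)) next
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(reads[idx]))
    cnt <- Biostrings::vcountPDict(pd, subj_all[usable])
    hits[idx] <- rowSums(cnt) > 0
  }
  hits
}

# Match reads against the mature catalog: a read matches a catalog entry
# when it aligns inside that entry full-length with at most `max_mismatch`
# substitutions (no indels), on the sense strand. Returns a list of matched
# catalog ids per read.
catalog_matches <- function(reads, catalog, max_mismatch = 2L) {
  out <- vector("list", length(reads))
  if (length(reads) == 0 || length(catalog) == 0) return(out)
  widths <- nchar(reads)
  cat_len <- nchar(catalog)
  for (w in unique(widths)) {
    idx <- which(widths == w)
    # enumerate all width-w windows of catalog entries
    ids <- character(0); subs <- character(0)
    for (k in seq_along(catalog)) {
      L <- cat_len[k]
      if (L < w) next
      off <- seq_len(L - w + 1L)
      subs <- c(subs, substring(catalog[k], off, off + w - 1L))
      ids <- c(ids, rep(names(catalog)[k], length(off)))
    }
    if (length(subs) == 0) next
    m <- seq_char_matrix(reads[idx])
    for (s in unique(subs)) {
      sv <- strsplit(s, "", fixed = TRUE)[[1]]
      mm <- rowSums(m != matrix(sv, nrow(m), w, byrow = TRUE))
      hit <- which(mm <= max_mismatch)
      if (length(hit)) {
        sids <- unique(ids[subs == s])
        for (h in hit)
          out[[idx[h]]] <- union(out[[idx[h]]], sids)
      }
    }
  }
  out
}

#' Hierarchical annotation of a small-RNA library
#'
#' Assigns each unique read to exactly one category by screening the
#' reference tiers in a fixed order: structural ncRNA, then repeats/mRNA,
#' then the mature miRNA catalog, then the genome; reads matching nowhere
#' are \code{unmapped}. Structural-ncRNA, repeat/mRNA and genome tiers use
#' exact substring matching on either strand; the miRNA-catalog tier allows
#' up to \code{mirbase_max_mismatch} substitutions (no indels) of the
#' full-length read within a catalog entry, on the sense strand. A read
#' keeps all catalog ids it matches (needed for family pooling) but its
#' category is decided by the tier order alone.
#'
#' @param reads a length-filtered \code{\link{library_reads}}.
#' @param refs a \code{\link{reference_set}}; empty components are skipped
#'   with a warning.
#' @param mirbase_max_mismatch substitutions tolerated at the catalog tier
#'   (default 2; 0 gives exact-match mode).
#' @return object of class \code{annotation_result}: list with
#'   \code{library_id}, \code{condition}, \code{counts},
#'   \code{category_of_read} (factor: noncoding, repeats_mrna, mirbase,
#'   genome, unmapped), \code{matched_mirna_ids} (list),
#'   \code{genome_mappable} (logical, genome hit at any tier) and
#'   \code{tally} (per-category total/unique counts).
#' @export
annotate_waterfall <- function(reads, refs, mirbase_max_mismatch = 2L) {
  stopifnot(inherits(reads, "library_reads"), inherits(refs, "reference_set"))
  seqs <- names(reads$counts)
  n <- length(seqs)
  for (comp in c("structural_ncrna", "repeats_mrna", "mature_catalog", "genome"))
    if (length(refs[[comp]]) == 0)
      warning("reference component '", comp, "' is empty; tier skipped",
              call. = FALSE)

  cat_lv <- c("noncoding", "repeats_mrna", "mirbase", "genome", "unmapped")
  category <- rep("unmapped", n)
  matched <- vector("list", n)

  genome_hit <- substring_hits(seqs, refs$genome, both_strands = TRUE)

  remaining <- rep(TRUE, n)
  nc <- substring_hits(seqs, refs$structural_ncrna, both_strands = TRUE)
  category[remaining & nc] <- "noncoding"
  remaining <- remaining & !nc

  rp <- substring_hits(seqs, refs$repeats_mrna, both_strands = TRUE)
  category[remaining & rp] <- "repeats_mrna"
  remaining <- remaining & !rp

  if (any(remaining) && length(refs$mature_catalog)) {
    idx <- which(remaining)
    mm <- catalog_matches(seqs[idx], refs$mature_catalog,
                          max_mismatch = mirbase_max_mismatch)
    hit <- lengths(mm) > 0
    category[idx[hit]] <- "mirbase"
    matched[idx[hit]] <- mm[hit]
    remaining[idx[hit]] <- FALSE
  }

  category[remaining & genome_hit] <- "genome"

  category <- factor(category, levels = cat_lv)
  tally <- data.frame(
    category = cat_lv,
    total = as.numeric(tapply(reads$counts, category, sum, default = 0)[cat_lv]),
    unique = as.numeric(table(category)[cat_lv]),
    stringsAsFactors = FALSE)
  tally$total[is.na(tally$total)] <- 0

  structure(list(library_id = reads$library_id,
                 condition = reads$condition,
                 replicate = reads$replicate,
                 counts = reads$counts,
                 category_of_read = setNames(category, seqs),
                 matched_mirna_ids = setNames(matched, seqs),
                 genome_mappable = setNames(genome_hit, seqs),
                 tally = tally),
            class = "annotation_result")
}

#' Per-library annotation tally table
#'
#' Combines per-library category tallies into one table with total and
#' unique read counts per category plus a Total row. Categories form a
#' disjoint partition (each read is counted in its waterfall category
#' only); the overlap-style "genome-mappable at any tier" counts are
#' attached as the \code{genome_any_tier} attribute.
#'
#' @param results list of \code{annotation_result}.
#' @return data frame with one \code{category} column and
#'   \code{total_<lib>} / \code{unique_<lib>} columns per library.
#' @export
tally_table <- function(results) {
  if (inherits(results, "annotation_result")) results <- list(results)
  cat_lv <- c("mirbase", "noncoding", "repeats_mrna", "genome", "unmapped")
  lab <- c(mirbase = "miRBase", noncoding = "Noncoding_RNA",
           repeats_mrna = "Repeats_mRNAs", genome = "Genome",
           unmapped = "Unmapped")
  out <- data.frame(category = c(lab[cat_lv], "Total"),
                    stringsAsFactors = FALSE)
  anytier <- data.frame(library_id = character(0), total = numeric(0),
                        unique = numeric(0))
  for (r in results) {
    t <- r$tally
    tot <- t$total[match(cat_lv, t$category)]
    uni <- t$unique[match(cat_lv, t$category)]
    out[[paste0("total_", r$library_id)]] <- c(tot, sum(tot))
    out[[paste0("unique_", r$library_id)]] <- c(uni, sum(uni))
    anytier <- rbind(anytier, data.frame(
      library_id = r$library_id,
      total = sum(r$counts[r$genome_mappable]),
      unique = sum(r$genome_mappable)))
  }
  attr(out, "genome_any_tier") <- anytier
  out
}
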