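#' Fold-back structure by base-pair maximization
#'
#' Predicts a nested secondary structure for a precursor sequence by
#' maximum-weight base pairing (Watson-Crick pairs weight 1, G:U wobble
#' pairs a configurable weight, default 1) with a minimum hairpin loop,
#' computed by dynamic programming with a deterministic traceback that
#' breaks ties toward pairing the 5'-most position first.
#'
#' An optional anchor interval marks the mature read within the
#' precursor: pairs joining the anchor to the rest of the sequence earn a
#' small score bonus and anchor-internal pairs are forbidden, so the
#' optimal structure pairs the mature arm outward before maximizing the
#' remaining pairs. Base-pair maximization over a long window is otherwise
#' highly degenerate, and an unanchored traceback routinely hands the
#' mature arm's partners to the flanks; the discovery stage therefore
#' always folds with the mature anchored.
#'
#' @param precursor DNA/RNA sequence (U is converted to T).
#' @param gu_weight weight of a G:U pair (0 disallows wobbles).
#' @param min_loop minimum hairpin loop length in nt (default 3).
#' @param anchor NULL, or 1-based inclusive \code{c(start, end)} of the
#'   mature read within the precursor.
#' @param anchor_bonus score bonus per anchor pair (small relative to 1 so
#'   it never trades away a real pair).
#' @return list with \code{partner} (1-based partner index per position, 0
#'   when unpaired), \code{score} (total pair weight), \code{n_pairs} and
#'   \code{dotbracket}.
#' @export
fold_back <- function(precursor, gu_weight = 1, min_loop = 3L,
                      anchor = NULL, anchor_bonus = 1e-3) {
  s <- normalize_seq(precursor)
  assert_dna(s, "precursor")
  a0 <- if (is.null(anchor)) c(-1L, -1L) else as.integer(anchor) - 1L
  res <- .nussinov_fold(s, gu_weight, as.integer(min_loop),
                        a0[1], a0[2], anchor_bonus)
  partner <- res$partner
  db <- rep(".", nchar(s))
  db[partner > seq_along(partner)] <- "("
  db[partner > 0 & partner < seq_along(partner)] <- ")"
  list(partner = partner, score = res$score,
       n_pairs = sum(partner > 0) / 2,
       dotbracket = paste(db, collapse = ""))
}

#' Map unannotated reads to the genome
#'
#' Exact-substring matching of reads on both genome strands. Minus-strand
#' hits are reported in forward-strand coordinates (0-based half-open)
#' with strand \code{-}. Reads hitting more than \code{max_loci} positions
#' are discarded as repetitive.
#'
#' @param reads character vector of read sequences, or a
#'   \code{library_reads}.
#' @param genome named character vector of chromosome sequences.
#' @param max_loci repetitive-read cutoff (default 5).
#' @return data frame read, chrom, start, end, strand; reads with no hit
#'   are absent, discarded repetitive reads are listed in the
#'   \code{repetitive} attribute.
#' @export
map_unannotated <- function(reads, genome, max_loci = 5L) {
  if (inherits(reads, "library_reads")) reads <- names(reads$counts)
  reads <- unique(normalize_seq(reads))
  rows <- list()
  for (chrom in names(genome)) {
    subject <- Biostrings::DNAString(genome[[chrom]])
    L <- nchar(genome[[chrom]])
    for (r in reads) {
      fw <- Biostrings::matchPattern(r, subject)
      for (st in BiocGenerics::start(fw))
        rows[[length(rows) + 1L]] <- data.frame(
          read = r, chrom = chrom, start = st - 1L,
          end = st - 1L + nchar(r), strand = "+",
          stringsAsFactors = FALSE)
      rc <- Biostrings::matchPattern(revcomp(r), subject)
      for (st in BiocGenerics::start(rc))
        rows[[length(rows) + 1L]] <- data.frame(
          read = r, chrom = chrom, start = st - 1L,
          end = st - 1L + nchar(r), strand = "-",
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    out <- data.frame(read = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
    attr(out, "repetitive") <- character(0)
    return(out)
  }
  out <- do.call(rbind, rows)
  nloci <- table(out$read)
  repetitive <- names(nloci)[nloci > max_loci]
  out <- out[!(out$read %in% repetitive), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "repetitive") <- repetitive
  out
}

#' Extract the candidate precursor window around a mapped read
#'
#' Takes \code{flank} nt upstream and downstream of the mapped region,
#' clipped at the chromosome ends. For minus-strand loci the returned
#' precursor sequence is the reverse complement of the window, while the
#' window coordinates stay on the forward strand.
#'
#' @param locus one-row data frame (or list) with chrom, start, end,
#'   strand (0-based half-open).
#' @param genome named character vector of chromosomes.
#' @param flank flanking length in nt (default 150).
#' @return list: \code{precursor} (sequence, 5'->3' on the read strand),
#'   \code{window_start}, \code{window_end} (forward-strand, 0-based
#'   half-open), \code{read_start}, \code{read_end} (1-based positions of
#'   the mapped read inside the precursor), \code{clipped} flag.
#' @export
extract_precursor <- function(locus, genome, flank = 150L) {
  chrom_seq <- genome[[locus$chrom]]
  L <- nchar(chrom_seq)
  ws <- max(0L, locus$start - flank)
  we <- min(L, locus$end + flank)
  window <- substr(chrom_seq, ws + 1L, we)
  clipped <- (locus$start - flank < 0) || (locus$end + flank > L)
  if (identical(locus$strand, "-")) {
    precursor <- revcomp(window)
    read_start <- we - locus$end + 1L
  } else {
    precursor <- window
    read_start <- locus$start - ws + 1L
  }
  list(precursor = precursor, window_start = ws, window_end = we,
       read_start = read_start,
       read_end = read_start + (locus$end - locus$start) - 1L,
       clipped = clipped)
}

#' Hairpin structure with the mature:star duplex located by scanning
#'
#' Builds the secondary structure used for candidate evaluation. The star
#' arm is located first by an ungapped complementarity scan: the region of
#' the precursor (away from the mature read by at least \code{min_loop}
#' nt) that base-pairs the most mature positions in antiparallel
#' orientation (G:U counted as pairing when \code{gu_weight > 0}) becomes
#' the duplex; ties prefer the region closest to the mature, then the
#' smallest coordinate. The duplex pairs are fixed and the remaining
#' intervals (outer flanks and the loop between the arms) are folded with
#' \code{\link{fold_back}}, giving a fully nested structure.
#'
#' Locating the duplex by scanning rather than from the unconstrained
#' maximum-pairing structure makes the evaluation deterministic and
#' robust: global base-pair maximization over a 300-nt window is massively
#' degenerate and routinely scatters the mature arm's partners across the
#' flanks, destroying real duplexes and occasionally fabricating spurious
#' ones.
#'
#' The duplex scan counts only Watson-Crick pairs by default
#' (\code{duplex_gu = FALSE}): under the strict reading of the hairpin
#' criteria a G:U wobble in the mature:star duplex counts as a mismatch.
#' This keeps chance complementarity in unstructured sequence well below
#' the mismatch threshold; set \code{duplex_gu = TRUE} to count wobbles as
#' pairs. The fill-in folding of the rest of the precursor always allows
#' wobbles according to \code{gu_weight}.
#'
#' @param precursor precursor sequence.
#' @param mature_start,mature_end 1-based inclusive mature position.
#' @param gu_weight,min_loop see \code{\link{fold_back}}.
#' @param duplex_gu count G:U as pairing in the duplex scan
#'   (default FALSE).
#' @return structure list as from \code{\link{fold_back}}, plus
#'   \code{duplex_pairs} (number of paired mature positions).
#' @export
hairpin_structure <- function(precursor, mature_start, mature_end,
                              gu_weight = 1, min_loop = 3L,
                              duplex_gu = FALSE) {
  s <- normalize_seq(precursor)
  L <- nchar(s)
  m <- substr(s, mature_start, mature_end)
  w <- nchar(m)
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  mv <- rev(strsplit(m, "", fixed = TRUE)[[1]])  # mature 3'->5'
  offs <- seq_len(L - w + 1L)
  # exclude star placements overlapping the mature or closer than min_loop
  ok <- (offs + w - 1L < mature_start - min_loop) |
        (offs > mature_end + min_loop)
  offs <- offs[ok]
  partner <- integer(L)
  npair <- 0L
  if (length(offs)) {
    counts <- vapply(offs, function(q) {
      tb <- v[q:(q + w - 1L)]
      sum(is_pair(mv, tb, gu = duplex_gu))
    }, integer(1))
    dist <- pmin(abs(offs - mature_end), abs(mature_start - (offs + w - 1L)))
    best <- offs[order(-counts, dist, offs)[1]]
    tb <- v[best:(best + w - 1L)]
    hit <- which(is_pair(mv, tb, gu = duplex_gu))
    # mv index t (1 = mature 3' end) sits at mature_end - t + 1 and pairs
    # precursor position best + t - 1
    for (t in hit) {
      i <- mature_end - t + 1L
      j <- best + t - 1L
      partner[i] <- j
      partner[j] <- i
    }
    npair <- length(hit)
  }
  # fill in the unconstrained intervals independently (keeps nesting);
  # mature positions stay out of the fill-in: their pairing status is
  # defined by the duplex scan alone
  paired_pos <- sort(unique(c(which(partner > 0),
                              mature_start:mature_end)))
  bounds <- c(0L, paired_pos, L + 1L)
  for (b in seq_len(length(bounds) - 1L)) {
    lo <- bounds[b] + 1L
    hi <- bounds[b + 1L] - 1L
    if (hi - lo + 1L >= min_loop + 2L) {
      sub <- fold_back(substr(s, lo, hi), gu_weight = gu_weight,
                       min_loop = min_loop)
      inside <- which(sub$partner > 0)
      partner[lo + inside - 1L] <- sub$partner[inside] + lo - 1L
    }
  }
  db <- rep(".", L)
  db[partner > seq_len(L)] <- "("
  db[partner > 0 & partner < seq_len(L)] <- ")"
  list(partner = partner, score = sum(partner > 0) / 2,
       n_pairs = sum(partner > 0) / 2,
       dotbracket = paste(db, collapse = ""),
       duplex_pairs = npair)
}

#' Score the mature:star duplex implied by a fold-back structure
#'
#' Locates the mature read on one arm of the predicted structure and
#' computes duplex metrics: number of unpaired mature positions
#' (mismatches), the longest asymmetric bulge between consecutive paired
#' mature positions, and the mature arm. The candidate passes when the
#' mature lies on a single arm (not across the loop), has at most
#' \code{max_mismatch} unpaired positions and no asymmetric bulge longer
#' than \code{max_bulge} nt.
#'
#' @param fold output of \code{\link{fold_back}} for the precursor.
#' @param mature_start,mature_end 1-based inclusive mature positions in
#'   the precursor.
#' @param max_mismatch maximum unpaired mature positions (default 4).
#' @param max_bulge maximum asymmetric bulge length in nt (default 2).
#' @return list: mismatches, bulge, arm ("5p"/"3p"/NA), pass, reason.
#' @export
evaluate_duplex <- function(fold, mature_start, mature_end,
                            max_mismatch = 4L, max_bulge = 2L) {
  idx <- mature_start:mature_end
  partner <- fold$partner[idx]
  paired <- which(partner > 0)
  fail <- function(reason) list(mismatches = NA_integer_, bulge = NA_integer_,
                                arm = NA_character_, pass = FALSE,
                                reason = reason)
  if (length(paired) < length(idx) / 2) return(fail("insufficient pairing"))
  p <- partner[paired]
  inside <- p >= mature_start & p <= mature_end
  if (any(inside)) return(fail("loop-spanning"))
  downstream <- p > mature_end
  if (!(all(downstream) || all(!downstream))) return(fail("loop-spanning"))
  arm <- if (all(downstream)) "5p" else "3p"
  mismatches <- length(idx) - length(paired)
  bulge <- 0L
  if (length(paired) >= 2) {
    for (k in seq_len(length(paired) - 1)) {
      gap_m <- paired[k + 1] - paired[k] - 1L
      gap_s <- abs(p[k] - p[k + 1]) - 1L
      bulge <- max(bulge, abs(gap_m - gap_s))
    }
  }
  list(mismatches = mismatches, bulge = bulge, arm = arm,
       pass = mismatches <= max_mismatch && bulge <= max_bulge,
       reason = if (mismatches > max_mismatch) "too many mismatches"
                else if (bulge > max_bulge) "asymmetric bulge"
                else "ok")
}

# star region implied by the duplex: the segment pairing the mature minus
# its 3'-terminal `overhang` nt, extended by `overhang` nt at the star 3'
# end. Returns 1-based inclusive [start, end] in precursor coordinates.
star_region <- function(fold, mature_start, mature_end, overhang = 2L) {
  partner <- fold$partner
  # nearest paired mature position at/inside each duplex end
  inner_end <- mature_end - overhang
  e <- inner_end
  while (e >= mature_start && partner[e] == 0) e <- e - 1L
  s <- mature_start
  while (s <= mature_end && partner[s] == 0) s <- s + 1L
  if (e < mature_start || s > mature_end || s > e) return(NULL)
  lo <- partner[e] - (inner_end - e)
  hi <- partner[s] + overhang + (s - mature_start)
  c(start = max(1L, min(lo, hi)), end = min(length(partner), max(lo, hi)))
}

#' Search the libraries for miRNA-star evidence
#'
#' A sequenced read counts as star evidence when it occurs in the
#' precursor with both ends within \code{tol} nt of the expected star
#' region (the positions pairing the mature read, shifted for the
#' \code{overhang}-nt 3' overhang). Returns the most abundant such read
#' pooled over libraries.
#'
#' @param precursor precursor sequence.
#' @param fold \code{\link{fold_back}} output.
#' @param mature_start,mature_end mature position (1-based inclusive).
#' @param libraries list of \code{library_reads}.
#' @param overhang duplex 3' overhang (default 2 nt).
#' @param tol positional tolerance on each star end (default 2 nt).
#' @return NULL, or list(sequence, start, end, counts, total).
#' @export
find_star <- function(precursor, fold, mature_start, mature_end, libraries,
                      overhang = 2L, tol = 2L) {
  reg <- star_region(fold, mature_start, mature_end, overhang)
  if (is.null(reg)) return(NULL)
  mature_seq <- substr(precursor, mature_start, mature_end)
  L <- nchar(precursor)
  # every precursor substring whose ends lie within tol of the star region
  grid <- expand.grid(st = (reg[["start"]] - tol):(reg[["start"]] + tol),
                      en = (reg[["end"]] - tol):(reg[["end"]] + tol))
  grid <- grid[grid$st >= 1 & grid$en <= L & grid$en > grid$st, , drop = FALSE]
  if (!nrow(grid)) return(NULL)
  cand <- substring(precursor, grid$st, grid$en)
  keep <- cand != mature_seq
  grid <- grid[keep, , drop = FALSE]; cand <- cand[keep]
  if (!length(cand)) return(NULL)
  totals <- numeric(length(cand))
  for (lr in libraries) {
    m <- match(cand, names(lr$counts))
    hit <- !is.na(m)
    totals[hit] <- totals[hit] + as.numeric(lr$counts[m[hit]])
  }
  if (all(totals == 0)) return(NULL)
  best <- order(-totals, cand, grid$st)[1]
  list(sequence = cand[best], start = grid$st[best], end = grid$en[best],
       total = totals[best])
}

#' Discover novel miRNA candidates from unannotated genome-mapped reads
#'
#' Orchestrates the discovery procedure for a set of candidate reads:
#' genome mapping, precursor window extraction, fold-back prediction,
#' duplex scoring and the star-strand search.
#'
#' @param reads named numeric vector: candidate read sequence -> pooled
#'   count across libraries.
#' @param genome named character vector of chromosomes.
#' @param libraries list of \code{library_reads}, searched for star reads.
#' @param flank precursor flank (default 150 nt).
#' @param max_loci repetitive-read cutoff (default 5).
#' @param min_count minimum pooled read count for a candidate (default 5).
#' @param gu_weight,min_loop folding parameters.
#' @param max_mismatch,max_bulge,overhang,tol duplex/star parameters.
#' @return data frame of candidates (one row per read x locus) with duplex
#'   metrics, star evidence and pass flags.
#' @export
hairpin_candidates <- function(reads, genome, libraries, flank = 150L,
                               max_loci = 5L, min_count = 5L,
                               gu_weight = 1, min_loop = 3L,
                               max_mismatch = 4L, max_bulge = 2L,
                               overhang = 2L, tol = 2L) {
  reads <- reads[reads >= min_count]
  if (!length(reads))
    return(empty_candidates())
  loci <- map_unannotated(names(reads), genome, max_loci = max_loci)
  if (!nrow(loci)) return(empty_candidates())
  rows <- vector("list", nrow(loci))
  for (i in seq_len(nrow(loci))) {
    loc <- loci[i, ]
    prec <- extract_precursor(loc, genome, flank = flank)
    fold <- hairpin_structure(prec$precursor, prec$read_start, prec$read_end,
                              gu_weight = gu_weight, min_loop = min_loop)
    ev <- evaluate_duplex(fold, prec$read_start, prec$read_end,
                          max_mismatch = max_mismatch, max_bulge = max_bulge)
    star <- NULL
    if (ev$pass)
      star <- find_star(prec$precursor, fold, prec$read_start, prec$read_end,
                        libraries, overhang = overhang, tol = tol)
    rows[[i]] <- data.frame(
      read = loc$read, count = as.numeric(reads[[loc$read]]),
      chrom = loc$chrom, start = loc$start, end = loc$end,
      strand = loc$strand,
      window_start = prec$window_start, window_end = prec$window_end,
      precursor = prec$precursor, dotbracket = fold$dotbracket,
      mature_arm = ev$arm %||% NA_character_,
      duplex_mismatches = ev$mismatches, duplex_bulge = ev$bulge,
      pass_duplex = ev$pass, fail_reason = ev$reason,
      star_seq = if (is.null(star)) NA_character_ else star$sequence,
      star_count = if (is.null(star)) 0 else star$total,
      has_star = !is.null(star),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_candidates <- function() {
  data.frame(read = character(0), count = numeric(0), chrom = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             window_start = integer(0), window_end = integer(0),
             precursor = character(0), dotbracket = character(0),
             mature_arm = character(0), duplex_mismatches = integer(0),
             duplex_bulge = integer(0), pass_duplex = logical(0),
             fail_reason = character(0), star_seq = character(0),
             star_count = numeric(0), has_star = logical(0),
             stringsAsFactors = FALSE)
}

#' Call novel miRNAs from evaluated hairpin candidates
#'
#' Keeps candidates that pass all duplex criteria and have sequenced star
#' support, then merges overlapping precursor windows on the same
#' chromosome into one locus, keeping the most abundant mature read.
#' Output ordering (chromosome, start, read) is deterministic.
#'
#' @param candidates output of \code{\link{hairpin_candidates}}.
#' @return data frame, one row per called novel miRNA locus.
#' @export
call_novel <- function(candidates) {
  ok <- candidates[candidates$pass_duplex & candidates$has_star, ,
                   drop = FALSE]
  if (!nrow(ok)) {
    ok$novel_id <- character(0)
    return(ok)
  }
  ok <- ok[order(ok$chrom, ok$start, ok$read), , drop = FALSE]
  group <- integer(nrow(ok))
  g <- 0L
  last_chrom <- ""
  last_end <- -1L
  for (i in seq_len(nrow(ok))) {
    if (ok$chrom[i] != last_chrom || ok$window_start[i] >= last_end) {
      g <- g + 1L
      last_chrom <- ok$chrom[i]
      last_end <- ok$window_end[i]
    } else last_end <- max(last_end, ok$window_end[i])
    group[i] <- g
  }
  keep <- vapply(split(seq_len(nrow(ok)), group), function(ii) {
    ii[order(-ok$count[ii], ok$read[ii])[1]]
  }, integer(1))
  out <- ok[sort(keep), , drop = FALSE]
  out$novel_id <- sprintf("novel-miR-%02d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' End-to-end novel miRNA discovery from annotated libraries
#'
#' Pools the genome-category reads of the annotated libraries and runs
#' \code{\link{hairpin_candidates}} plus \code{\link{call_novel}}.
#'
#' @param anns list of \code{annotation_result}.
#' @param refs \code{reference_set} (genome used for mapping).
#' @param libraries list of \code{library_reads} searched for star reads
#'   (default: reconstructed from \code{anns}).
#' @param ... passed to \code{\link{hairpin_candidates}}.
#' @return list with \code{candidates} and \code{novel} data frames.
#' @export
discover_novel <- function(anns, refs, libraries = NULL, ...) {
  if (inherits(anns, "annotation_result")) anns <- list(anns)
  if (is.null(libraries))
    libraries <- lapply(anns, function(a)
      library_reads(a$library_id, a$condition, a$replicate, a$counts))
  seqs <- unlist(lapply(anns, function(a)
    names(a$counts)[a$category_of_read == "genome"]), use.names = FALSE)
  cnts <- unlist(lapply(anns, function(a)
    as.numeric(a$counts[a$category_of_read == "genome"])), use.names = FALSE)
  pooled <- if (length(seqs)) {
    agg <- rowsum(cnts, seqs)
    setNames(agg[, 1], rownames(agg))
  } else setNames(numeric(0), character(0))
  cand <- hairpin_candidates(pooled, refs$genome, libraries, ...)
  list(candidates = cand, novel = call_novel(cand))
}
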