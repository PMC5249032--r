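#' Canonical miRNA family of a miRNA identifier
#'
#' Collapses member ids such as \code{gma-miR156b-5p} to the family name
#' \code{MIR156}: the species prefix, variant letters, arm suffix and any
#' star mark are stripped and the numeric part is kept. Ids already in
#' \code{MIR<number>} form are returned with any trailing qualifiers
#' removed (so \code{MIR1512} is idempotent). Ids that match neither
#' pattern are returned unchanged and flagged in the \code{unparsed}
#' attribute.
#'
#' @param mirna_id character vector of miRNA identifiers.
#' @return character vector of family ids with an \code{unparsed} logical
#'   attribute.
#' @export
family_of <- function(mirna_id) {
  x <- sub("\\*$", "", mirna_id)
  out <- character(length(x))
  p_member <- "^[A-Za-z]{2,5}[-_]miR-?(\\d+).*$"
  p_family <- "^MIR(\\d+).*$"
  is_m <- grepl(p_member, x)
  is_f <- !is_m & grepl(p_family, x)
  out[is_m] <- paste0("MIR", sub(p_member, "\\1", x[is_m]))
  out[is_f] <- paste0("MIR", sub(p_family, "\\1", x[is_f]))
  unparsed <- !is_m & !is_f
  out[unparsed] <- mirna_id[unparsed]
  attr(out, "unparsed") <- unparsed
  out
}

#' Reads-per-ten-million normalization
#'
#' RPTM = count x 10^7 / library denominator.
#'
#' @param counts numeric vector (or matrix with libraries in columns).
#' @param denominators per-library totals; recycled across \code{counts}
#'   columns when \code{counts} is a matrix.
#' @return normalized values with the shape of \code{counts}.
#' @export
rptm_normalize <- function(counts, denominators) {
  if (any(denominators <= 0))
    stop("library denominators must be positive", call. = FALSE)
  if (is.matrix(counts)) {
    if (length(denominators) != ncol(counts))
      stop("one denominator per library column required", call. = FALSE)
    sweep(counts, 2, denominators, "/") * 1e7
  } else counts * 1e7 / denominators
}

TIER_LEVELS <- c("extremely_low", "low", "moderate", "high")

#' Abundance tier of a mean RPTM value
#'
#' Four tiers with lower-closed boundaries: high (>= 100,000 RPTM),
#' moderate ([10,000, 100,000)), low ([1,000, 10,000)) and extremely low
#' ([0, 1,000)).
#'
#' @param mean_rptm non-negative numeric vector.
#' @return ordered factor with levels extremely_low < low < moderate < high.
#' @export
classify_tier <- function(mean_rptm) {
  if (any(mean_rptm < 0)) stop("mean RPTM must be >= 0", call. = FALSE)
  cut(mean_rptm, breaks = c(-Inf, 1000, 10000, 100000, Inf),
      labels = TIER_LEVELS, right = FALSE, ordered_result = TRUE)
}

# per-library denominators for RPTM
# mode "filtered": total retained (length-filtered) reads;
# mode "genome": genome-mappable (any tier) totals
#' RPTM denominators from annotated libraries
#' @param anns list of \code{annotation_result}.
#' @param mode \code{"filtered"} (total retained reads, default) or
#'   \code{"genome"} (genome-mappable at any tier).
#' @return named numeric vector by library id.
#' @export
library_denominators <- function(anns, mode = c("filtered", "genome")) {
  mode <- match.arg(mode)
  vapply(anns, function(a) {
    if (mode == "filtered") sum(a$counts) else sum(a$counts[a$genome_mappable])
  }, numeric(1), USE.NAMES = FALSE) |>
    setNames(vapply(anns, `[[`, character(1), "library_id"))
}

is_star_id <- function(ids) grepl("\\*$", ids)

#' Per-miRNA abundance profiles
#'
#' Sums, per library, the counts of all reads matched to each catalog
#' entry (a read matching several entries contributes to each) and
#' normalizes to RPTM.
#'
#' @param anns list of \code{annotation_result} (one per library).
#' @param denominators named per-library totals for RPTM (default: total
#'   retained reads via \code{\link{library_denominators}}).
#' @return data frame with mirna_id, family_id, is_star, and per-library
#'   \code{raw_<lib>} and \code{rptm_<lib>} columns.
#' @export
mirna_profile_table <- function(anns, denominators = NULL) {
  if (inherits(anns, "annotation_result")) anns <- list(anns)
  if (is.null(denominators)) denominators <- library_denominators(anns)
  ids <- sort(unique(unlist(lapply(anns, function(a)
    unlist(a$matched_mirna_ids, use.names = FALSE)))))
  out <- data.frame(mirna_id = ids,
                    family_id = as.character(family_of(ids)),
                    is_star = is_star_id(ids),
                    stringsAsFactors = FALSE)
  for (a in anns) {
    raw <- setNames(numeric(length(ids)), ids)
    hit <- which(lengths(a$matched_mirna_ids) > 0)
    for (i in hit) {
      for (id in a$matched_mirna_ids[[i]])
        raw[id] <- raw[id] + a$counts[i]
    }
    out[[paste0("raw_", a$library_id)]] <- as.numeric(raw)
    out[[paste0("rptm_", a$library_id)]] <-
      rptm_normalize(as.numeric(raw), denominators[[a$library_id]])
  }
  out
}

#' Family-level abundance profiles with abundance tiers
#'
#' Pools, per library, the counts of all reads assigned to each miRNA
#' family (each read counted once per family regardless of how many family
#' members it matches), normalizes to RPTM and classifies each family into
#' an abundance tier from its mean RPTM. Star-strand reads (catalog ids
#' ending in \code{*}) are excluded from family totals by default and
#' reported separately by \code{\link{star_summary}}.
#'
#' @param anns list of \code{annotation_result}.
#' @param denominators named per-library totals for RPTM.
#' @param include_star pool star-strand reads into family totals
#'   (default FALSE).
#' @param tier_libraries library ids over which the tier-defining mean RPTM
#'   is taken; default: the control libraries (all libraries if none are
#'   labelled control).
#' @return data frame with family_id, member_ids, per-library raw/rptm
#'   columns, mean_rptm_control, mean_rptm_stress and tier.
#' @export
family_profile_table <- function(anns, denominators = NULL,
                                 include_star = FALSE,
                                 tier_libraries = NULL) {
  if (inherits(anns, "annotation_result")) anns <- list(anns)
  if (is.null(denominators)) denominators <- library_denominators(anns)
  lib_ids <- vapply(anns, `[[`, character(1), "library_id")
  conds <- vapply(anns, `[[`, character(1), "condition")

  fam_rows <- list()
  for (a in anns) {
    hit <- which(lengths(a$matched_mirna_ids) > 0)
    for (i in hit) {
      ids <- a$matched_mirna_ids[[i]]
      if (!include_star) ids <- ids[!is_star_id(ids)]
      if (!length(ids)) next
      fams <- unique(as.character(family_of(ids)))
      for (f in fams)
        fam_rows[[f]] <- unique(c(fam_rows[[f]], ids[family_of(ids) == f]))
    }
  }
  fams <- sort(names(fam_rows))
  out <- data.frame(family_id = fams,
                    member_ids = vapply(fam_rows[fams], function(x)
                      paste(sort(x), collapse = ","), character(1)),
                    stringsAsFactors = FALSE)
  rptm_mat <- matrix(0, nrow = length(fams), ncol = length(anns),
                     dimnames = list(fams, lib_ids))
  for (j in seq_along(anns)) {
    a <- anns[[j]]
    raw <- setNames(numeric(length(fams)), fams)
    hit <- which(lengths(a$matched_mirna_ids) > 0)
    for (i in hit) {
      ids <- a$matched_mirna_ids[[i]]
      if (!include_star) ids <- ids[!is_star_id(ids)]
      if (!length(ids)) next
      for (f in unique(as.character(family_of(ids))))
        raw[f] <- raw[f] + a$counts[i]
    }
    rptm <- rptm_normalize(as.numeric(raw), denominators[[a$library_id]])
    rptm_mat[, j] <- rptm
    out[[paste0("raw_", a$library_id)]] <- as.numeric(raw)
    out[[paste0("rptm_", a$library_id)]] <- rptm
  }
  ctrl <- lib_ids[conds == "control"]
  strs <- lib_ids[conds == "water_stress"]
  if (is.null(tier_libraries))
    tier_libraries <- if (length(ctrl)) ctrl else lib_ids
  out$mean_rptm_control <- if (length(ctrl))
    rowMeans(rptm_mat[, ctrl, drop = FALSE]) else NA_real_
  out$mean_rptm_stress <- if (length(strs))
    rowMeans(rptm_mat[, strs, drop = FALSE]) else NA_real_
  out$tier <- classify_tier(rowMeans(rptm_mat[, tier_libraries, drop = FALSE]))
  rownames(out) <- NULL
  out
}

#' Star versus mature strand abundance summary
#'
#' For each family, totals mature-strand and star-strand RPTM (summed over
#' libraries) and their ratio. Families whose mature RPTM is 0 have an
#' undefined ratio and are flagged.
#'
#' @param profiles output of \code{\link{mirna_profile_table}}.
#' @return data frame: family_id, mature_rptm, star_rptm, star_mature_ratio,
#'   ratio_undefined.
#' @export
star_summary <- function(profiles) {
  rptm_cols <- grep("^rptm_", names(profiles), value = TRUE)
  tot <- rowSums(profiles[, rptm_cols, drop = FALSE])
  fam <- profiles$family_id
  mature <- tapply(ifelse(profiles$is_star, 0, tot), fam, sum)
  star <- tapply(ifelse(profiles$is_star, tot, 0), fam, sum)
  fams <- sort(unique(fam))
  out <- data.frame(family_id = fams,
                    mature_rptm = as.numeric(mature[fams]),
                    star_rptm = as.numeric(star[fams]),
                    stringsAsFactors = FALSE)
  out$star_mature_ratio <- ifelse(out$mature_rptm > 0,
                                  out$star_rptm / out$mature_rptm, NA_real_)
  out$ratio_undefined <- out$mature_rptm == 0
  out
}
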