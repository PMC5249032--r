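#' Pooled-RPTM log2 fold change
#'
#' log2 of the stress-to-control ratio of pooled (summed) per-library RPTM
#' values. A pseudocount is added to both pooled sums only when either sum
#' is zero, so features with counts in both conditions reproduce the plain
#' ratio exactly.
#'
#' @param control_rptm,stress_rptm non-negative per-library values.
#' @param pseudocount value added to both pooled sums when either is 0.
#' @return log2 fold change; NA (flagged, not an error) when both pooled
#'   sums are zero.
#' @export
log_fold_change <- function(control_rptm, stress_rptm, pseudocount = 0.5) {
  if (!length(control_rptm) || !length(stress_rptm))
    stop("both condition vectors must be non-empty", call. = FALSE)
  if (any(c(control_rptm, stress_rptm) < 0))
    stop("abundances must be >= 0", call. = FALSE)
  a <- sum(stress_rptm)
  b <- sum(control_rptm)
  if (a == 0 && b == 0) return(NA_real_)
  if (a == 0 || b == 0) {
    a <- a + pseudocount
    b <- b + pseudocount
  }
  log2(a / b)
}

# conditional NB log-likelihood of one feature's counts within one group,
# given their total, at dispersion phi (size r = 1/phi per library)
cond_ll_group <- function(y, phi) {
  n <- length(y)
  if (n < 2) return(0)
  z <- sum(y)
  if (z == 0) return(0)
  if (phi <= 0) {
    # Poisson limit: multinomial with equal cell probabilities
    return(lgamma(z + 1) - sum(lgamma(y + 1)) - z * log(n))
  }
  r <- 1 / phi
  sum(lgamma(y + r)) - n * lgamma(r) - lgamma(z + n * r) + lgamma(n * r) +
    lgamma(z + 1) - sum(lgamma(y + 1))
}

# scale counts to a common library size (geometric mean), rounding to
# integers; the exact test and dispersion estimator both work on these
# equalized pseudo-counts
equalize_counts <- function(counts, lib_sizes) {
  common <- exp(mean(log(lib_sizes)))
  t(t(counts) * (common / lib_sizes))
}

#' Common negative-binomial dispersion by conditional likelihood
#'
#' Estimates a single dispersion shared by all features, maximizing the
#' sum over features and conditions of the within-group conditional NB
#' log-likelihood after scaling all libraries to a common size. Returns 0
#' for under-dispersed (at-or-below-Poisson) data.
#'
#' @param counts feature-by-library matrix of non-negative counts.
#' @param condition factor/character of column conditions.
#' @param lib_sizes per-library totals (default: column sums).
#' @return dispersion estimate (variance = mu + dispersion * mu^2).
#' @export
estimate_dispersion <- function(counts, condition,
                                lib_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  condition <- as.character(condition)
  reps <- table(condition)
  if (all(reps < 2))
    stop(paste("no condition has replicates; supply a fixed dispersion to",
               "the exact test instead"), call. = FALSE)
  eq <- round(equalize_counts(counts, lib_sizes))
  groups <- split(seq_along(condition), condition)
  groups <- groups[vapply(groups, length, integer(1)) >= 2]
  obj <- function(log_phi) {
    phi <- exp(log_phi)
    ll <- 0
    for (g in groups)
      ll <- ll + sum(apply(eq[, g, drop = FALSE], 1, cond_ll_group, phi = phi))
    ll
  }
  opt <- optimize(obj, interval = log(c(1e-6, 10)), maximum = TRUE,
                  tol = 1e-4)
  phi <- exp(opt$maximum)
  # boundary: likelihood not better than the Poisson limit -> 0
  ll0 <- sum(unlist(lapply(groups, function(g)
    apply(eq[, g, drop = FALSE], 1, cond_ll_group, phi = 0))))
  if (phi < 2e-6 || opt$objective <= ll0 + 1e-8) 0 else phi
}

#' Exact negative-binomial test for one feature
#'
#' Two-sided exact test comparing the condition-pooled counts of one
#' feature after scaling all libraries to a common size: conditional on
#' the pooled total, the probability of each split between conditions is
#' negative-binomial (Poisson/binomial in the dispersion-0 limit), and the
#' p-value sums the probabilities of all splits at most as likely as the
#' observed one.
#'
#' @param y per-library counts of the feature.
#' @param condition two-level factor/character over libraries.
#' @param dispersion common NB dispersion (0 gives the binomial limit).
#' @param lib_sizes per-library totals used for equalization.
#' @return two-sided p-value.
#' @export
exact_test <- function(y, condition, dispersion,
                       lib_sizes = rep(1, length(y))) {
  condition <- as.character(condition)
  lv <- unique(condition)
  if (length(lv) != 2) stop("exactly two conditions required", call. = FALSE)
  ye <- round(as.numeric(equalize_counts(matrix(y, nrow = 1), lib_sizes)))
  a_obs <- sum(ye[condition == lv[1]])
  b_obs <- sum(ye[condition == lv[2]])
  t_tot <- a_obs + b_obs
  if (t_tot == 0) return(1)
  n_a <- sum(condition == lv[1])
  n_b <- sum(condition == lv[2])
  mu <- t_tot / (n_a + n_b)
  x <- 0:t_tot
  logp <- if (dispersion <= 0) {
    stats::dbinom(x, t_tot, n_a / (n_a + n_b), log = TRUE)
  } else {
    r <- 1 / dispersion
    lp <- stats::dnbinom(x, mu = n_a * mu, size = n_a * r, log = TRUE) +
      stats::dnbinom(t_tot - x, mu = n_b * mu, size = n_b * r, log = TRUE)
    lp - log(sum(exp(lp - max(lp)))) - max(lp)
  }
  p_obs <- logp[a_obs + 1]
  min(1, sum(exp(logp[logp <= p_obs + 1e-9] - p_obs) * exp(p_obs)))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; input values are validated to lie in [0, 1].
#'
#' @param pvalues numeric vector in [0, 1].
#' @return adjusted values (same order as input).
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(pvalues, method = "BH")
}

#' Stringent and relaxed differential-expression calls
#'
#' Stringent: \code{up} when logFC >= \code{lfc_min} and FDR <
#' \code{fdr_max}; \code{down} symmetric; otherwise \code{ns}. The relaxed
#' call applies the fold-change threshold only.
#'
#' @param results data frame with \code{logFC} and \code{fdr} columns.
#' @param lfc_min absolute log2 fold-change threshold (default 1).
#' @param fdr_max FDR threshold (default 0.05).
#' @return \code{results} with \code{call} and \code{relaxed_call} columns.
#' @export
call_de <- function(results, lfc_min = 1.0, fdr_max = 0.05) {
  lfc <- results$logFC
  fdr <- results$fdr
  call <- rep("ns", nrow(results))
  call[!is.na(lfc) & lfc >= lfc_min & fdr < fdr_max] <- "up"
  call[!is.na(lfc) & lfc <= -lfc_min & fdr < fdr_max] <- "down"
  relaxed <- rep("ns", nrow(results))
  relaxed[!is.na(lfc) & lfc >= lfc_min] <- "up"
  relaxed[!is.na(lfc) & lfc <= -lfc_min] <- "down"
  results$call <- factor(call, levels = c("up", "down", "ns"))
  results$relaxed_call <- factor(relaxed, levels = c("up", "down", "ns"))
  results
}

#' Differential-expression test over a count matrix
#'
#' Runs the common-dispersion estimate, the per-feature exact NB test and
#' BH-FDR over a feature-by-library count matrix, computing the log2 fold
#' change from pooled RPTM values and a mean-abundance column (log2 of the
#' mean counts-per-million).
#'
#' @param counts feature-by-library matrix of raw counts (rownames =
#'   feature ids).
#' @param condition conditions per column (two levels; the level named
#'   \code{"control"}, or the first level, is the reference).
#' @param lib_sizes per-library totals (default: column sums).
#' @param dispersion fixed dispersion; estimated when NULL.
#' @param lfc_min,fdr_max call thresholds (see \code{\link{call_de}}).
#' @param pseudocount see \code{\link{log_fold_change}}.
#' @return data frame: feature_id, logFC, mean_abundance, pvalue, fdr,
#'   call, relaxed_call; dispersion in the \code{dispersion} attribute.
#' @export
de_test <- function(counts, condition, lib_sizes = colSums(counts),
                    dispersion = NULL, lfc_min = 1.0, fdr_max = 0.05,
                    pseudocount = 0.5) {
  counts <- as.matrix(counts)
  condition <- as.character(condition)
  lv <- unique(condition)
  if (length(lv) != 2) stop("exactly two conditions required", call. = FALSE)
  ref <- if ("control" %in% lv) "control" else lv[1]
  alt <- setdiff(lv, ref)
  if (is.null(dispersion))
    dispersion <- estimate_dispersion(counts, condition, lib_sizes)
  rptm <- rptm_normalize(counts, lib_sizes)
  lfc <- vapply(seq_len(nrow(counts)), function(i)
    log_fold_change(rptm[i, condition == ref], rptm[i, condition == alt],
                    pseudocount = pseudocount), numeric(1))
  cpm <- rptm / 10
  p <- vapply(seq_len(nrow(counts)), function(i)
    exact_test(counts[i, ], condition, dispersion, lib_sizes), numeric(1))
  out <- data.frame(feature_id = rownames(counts) %||%
                      as.character(seq_len(nrow(counts))),
                    logFC = lfc,
                    mean_abundance = log2(rowMeans(cpm) + 0.25),
                    pvalue = p,
                    fdr = bh_fdr(p),
                    stringsAsFactors = FALSE)
  out <- call_de(out, lfc_min = lfc_min, fdr_max = fdr_max)
  attr(out, "dispersion") <- dispersion
  rownames(out) <- NULL
  out
}
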