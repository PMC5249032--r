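# Independent oracles used by the property tests. These deliberately use
# naive formulations (explicit recursion, per-offset loops) so they share
# no code path with the package implementations they check.

oracle_pairs_ok <- function(a, b, gu = TRUE) {
  p <- paste0(a, b)
  p %in% c("AT", "TA", "CG", "GC") || (gu && p %in% c("GT", "TG"))
}

# maximum pair count over all nested structures with min loop 3,
# by exhaustive recursion over "position i unpaired / i paired with k"
oracle_max_pairs <- function(s, gu = TRUE) {
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  rec <- function(i, j) {
    if (j - i < 4) return(0)
    best <- rec(i + 1, j)
    for (k in (i + 4):j)
      if (oracle_pairs_ok(v[i], v[k], gu))
        best <- max(best, 1 + rec(i + 1, k - 1) + rec(k + 1, j))
    best
  }
  rec(1, length(v))
}

# naive target scan: per offset, per position mismatch/wobble counting
oracle_scan <- function(mirna, transcript, wobble_weight = 0.5) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  mv <- strsplit(mirna, "", fixed = TRUE)[[1]]
  tv <- strsplit(transcript, "", fixed = TRUE)[[1]]
  w <- length(mv)
  L <- length(tv)
  if (L < w) return(data.frame(position = integer(0), mismatches = integer(0),
                               wobbles = integer(0), score = numeric(0)))
  out <- NULL
  for (s in 1:(L - w + 1)) {
    mm <- 0L; wb <- 0L
    for (k in 1:w) {
      tb <- tv[s + w - k]       # antiparallel: miRNA pos k pairs here
      m <- mv[k]
      if (tb == comp[[m]]) {
      } else if ((m == "G" && tb == "T") || (m == "T" && tb == "G")) {
        wb <- wb + 1L
      } else mm <- mm + 1L
    }
    out <- rbind(out, data.frame(position = s - 1L, mismatches = mm,
                                 wobbles = wb,
                                 score = mm + wobble_weight * wb))
  }
  out
}
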