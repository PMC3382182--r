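# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: plain position sets, full quadratic DP, direct formulas.

# Smith-Waterman local alignment score, affine gaps costing
# open + len * extend (matches the package's search parameterisation).
sw_score_oracle <- function(a, b, submat, open = 11, extend = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)  # gap in b (consume a)
  Y <- matrix(-Inf, n + 1, m + 1)  # gap in a (consume b)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[av[i - 1], bv[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1] + s, X[i - 1, j - 1] + s,
                     Y[i - 1, j - 1] + s)
      X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend)
      Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend)
      best <- max(best, M[i, j])
    }
  }
  best
}

# Classical tie-free Spearman formula 1 - 6*sum(d^2)/(n(n^2-1)).
spearman_formula_oracle <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Position-set union oracle for merged alignments: per-nucleotide ownership
# by the highest-scoring hit covering it (ties: lowest qstart, then qend).
merge_oracle <- function(hits) {
  ord <- order(-hits$score, hits$qstart, hits$qend)
  all_pos <- sort(unique(unlist(lapply(seq_len(nrow(hits)), function(i)
    hits$qstart[i]:hits$qend[i]))))
  dens <- vapply(all_pos, function(p) {
    covering <- ord[hits$qstart[ord] <= p & hits$qend[ord] >= p]
    top <- covering[1]
    min(1, 3 * hits$matches[top] / (hits$qend[top] - hits$qstart[top] + 1))
  }, 0)
  list(L = as.integer(round(length(all_pos) / 3)),
       I = min(1, sum(dens) / length(all_pos)))
}

# Triple-filter scan oracle for variant calls.
call_variants_oracle <- function(columns, min_cov = 5, min_alt = 2,
                                 min_freq = 0.15) {
  out <- 0L
  for (i in seq_len(nrow(columns))) {
    if (columns$depth[i] < min_cov) next
    for (b in c("A", "C", "G", "T")) {
      if (b == columns$ref[i]) next
      cnt <- columns[[b]][i]
      if (cnt >= min_alt && cnt / columns$depth[i] >= min_freq)
        out <- out + 1L
    }
  }
  out
}

# Covered-bp oracle: per-base boolean OR over alignment ref spans.
covered_bp_oracle <- function(starts, ends, len) {
  covered <- logical(len)
  for (i in seq_along(starts)) covered[(starts[i] + 1):ends[i]] <- TRUE
  sum(covered)
}
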