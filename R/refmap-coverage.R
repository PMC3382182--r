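# Coverage, consensus and window analytics over reference-mapped reads.

BASE_IDX <- c(A = 1L, C = 2L, G = 3L, T = 4L)

# Per-chromosome 5 x L base-count matrices (A,C,G,T,gap) from alignments.
base_count_matrices <- function(alignments, ref) {
  out <- lapply(ref$chromosomes, function(s)
    matrix(0L, nrow = 5L, ncol = nchar(s)))
  if (nrow(alignments) == 0L) return(out)
  for (i in seq_len(nrow(alignments))) {
    cid <- alignments$chrom[i]
    cigar <- alignments$cigar[i]
    start <- alignments$start[i]
    rseq <- alignments$seq[i]
    if (grepl("^[0-9]+M$", cigar)) {
      n <- nchar(rseq)
      refpos <- start + seq_len(n)
      b <- BASE_IDX[seq_chars(rseq)]
    } else {
      pr <- cigar_pairs(cigar, start)
      refpos <- pr$ref + 1L
      b <- BASE_IDX[seq_chars(rseq)[pr$qry + 1L]]
      if (length(pr$del)) {
        idx5 <- 5L + (pr$del) * 5L
        out[[cid]][idx5] <- out[[cid]][idx5] + 1L
      }
    }
    keep <- !is.na(b)
    idx <- b[keep] + (refpos[keep] - 1L) * 5L
    out[[cid]][idx] <- out[[cid]][idx] + 1L
  }
  out
}

# Reference-spanning depth (M + D columns) per chromosome.
depth_vectors <- function(alignments, ref) {
  lens <- chrom_lengths(ref)
  out <- lapply(lens, function(L) integer(L))
  if (nrow(alignments) == 0L) return(out)
  unknown <- setdiff(unique(alignments$chrom), names(lens))
  assert_that(length(unknown) == 0, "alignments reference unknown chromosome: %s",
              paste(unknown, collapse = ", "))
  for (cid in unique(alignments$chrom)) {
    a <- alignments[alignments$chrom == cid]
    cov <- IRanges::coverage(IRanges::IRanges(a$start + 1L, a$end),
                             width = lens[[cid]])
    out[[cid]] <- as.integer(cov)
  }
  out
}

#' Consensus sequence from mapped reads
#'
#' Majority base per covered column; ties and zero-coverage columns fall
#' back to the reference base (uncovered columns are flagged), so consensus
#' coordinates stay reference-projected. Insertions are reported as events,
#' not columns.
#'
#' @param alignments alignment `data.table` (see [map_reads()]).
#' @param ref a `ReferenceGenome`.
#' @return list with `consensus` (named character vector), `depth`
#'   (list of per-base read depth), `uncovered` (list of logical vectors),
#'   and `insertions` (`data.table`).
#' @export
consensus_sequences <- function(alignments, ref) {
  counts <- base_count_matrices(alignments, ref)
  depth <- depth_vectors(alignments, ref)
  cons <- character(length(ref$chromosomes))
  names(cons) <- names(ref$chromosomes)
  uncovered <- list()
  for (cid in names(ref$chromosomes)) {
    refb <- seq_chars(ref$chromosomes[[cid]])
    m <- counts[[cid]][1:4, , drop = FALSE]
    top <- max.col(t(m), ties.method = "first")
    topn <- m[top + (seq_len(ncol(m)) - 1L) * 4L]
    nties <- colSums(m == rep(topn, each = 4L)) > 1L
    base <- names(BASE_IDX)[top]
    use_ref <- topn == 0L | nties
    base[use_ref] <- refb[use_ref]
    cons[cid] <- paste(base, collapse = "")
    uncovered[[cid]] <- depth[[cid]] == 0L
  }
  ins <- insertion_events(alignments)
  list(consensus = cons, depth = depth, uncovered = uncovered,
       insertions = ins)
}

insertion_events <- function(alignments) {
  rows <- list()
  if (nrow(alignments)) {
    with_i <- which(grepl("I", alignments$cigar, fixed = TRUE))
    for (i in with_i) {
      pr <- cigar_pairs(alignments$cigar[i], alignments$start[i])
      if (length(pr$ins))
        rows[[length(rows) + 1L]] <- data.table::data.table(
          chrom = alignments$chrom[i], pos = pr$ins,
          read_id = alignments$read_id[i])
    }
  }
  if (length(rows)) data.table::rbindlist(rows)
  else data.table::data.table(chrom = character(), pos = integer(),
                              read_id = character())
}

#' Per-chromosome coverage profile
#'
#' Computes, per chromosome and genome-wide: read count, covered bp,
#' coverage fraction (share of bases with depth >= 1), coverage depth (mean
#' depth), and percent identical sites (consensus equal to reference,
#' evaluated over read-covered columns only).
#'
#' @param alignments alignment `data.table`.
#' @param ref a `ReferenceGenome`.
#' @param identity compute the consensus-based identical-sites column
#'   (needs `seq` + `cigar` in `alignments`).
#' @return a `CoverageProfile`: list with `summary` (`data.table`), `depth`
#'   (per-chromosome vectors), and `consensus` (when `identity = TRUE`).
#' @export
coverage_profile <- function(alignments, ref, identity = TRUE) {
  lens <- chrom_lengths(ref)
  depth <- depth_vectors(alignments, ref)
  cons <- if (identity && nrow(alignments)) consensus_sequences(alignments, ref)
  rows <- lapply(names(lens), function(cid) {
    d <- depth[[cid]]
    covered <- sum(d > 0L)
    ident <- NA_real_
    if (!is.null(cons) && covered > 0L) {
      cc <- seq_chars(cons$consensus[[cid]])
      rr <- seq_chars(ref$chromosomes[[cid]])
      on_cov <- d > 0L
      ident <- 100 * sum(cc[on_cov] == rr[on_cov]) / covered
    }
    data.table::data.table(
      chrom = cid, category = ref$category[[cid]], length = lens[[cid]],
      reads = sum(alignments$chrom == cid),
      covered_bp = covered,
      coverage_fraction = covered / lens[[cid]],
      coverage_depth = mean(d),
      identical_sites_pct = ident,
      gc = gc_content(ref$chromosomes[[cid]]))
  })
  summary <- data.table::rbindlist(rows)
  structure(list(summary = summary, depth = depth, consensus = cons,
                 genome_coverage_fraction =
                   sum(summary$covered_bp) / sum(summary$length),
                 genome_coverage_depth =
                   sum(vapply(depth, sum, 0)) / sum(summary$length)),
            class = "CoverageProfile")
}

#' @export
print.CoverageProfile <- function(x, ...) {
  cat(sprintf(
    "CoverageProfile: %d chromosomes, genome coverage %.1f%%, depth %.2fx\n",
    nrow(x$summary), 100 * x$genome_coverage_fraction,
    x$genome_coverage_depth))
  invisible(x)
}

#' Windowed GC / mean-depth tracks
#'
#' @param profile a `CoverageProfile`.
#' @param ref the `ReferenceGenome` used to build it.
#' @param window window size in bp (>= 100); the last partial window keeps
#'   its true length.
#' @return `data.table` with `chrom`, `start`, `end` (0-based half-open),
#'   `gc`, `mean_depth`.
#' @export
window_tracks <- function(profile, ref, window = 5000L) {
  assert_that(window >= 100, "window must be >= 100 bp")
  rows <- lapply(names(ref$chromosomes), function(cid) {
    L <- nchar(ref$chromosomes[[cid]])
    starts <- seq(0L, L - 1L, by = window)
    ends <- pmin(starts + window, L)
    d <- profile$depth[[cid]]
    data.table::data.table(
      chrom = cid, start = starts, end = ends,
      gc = gc_content(substring(ref$chromosomes[[cid]], starts + 1L, ends)),
      mean_depth = vapply(seq_along(starts), function(i)
        mean(d[(starts[i] + 1L):ends[i]]), 0))
  })
  data.table::rbindlist(rows)
}
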