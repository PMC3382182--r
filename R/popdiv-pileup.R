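#' Pileup of mapped reads over a region
#'
#' Per-column base counts (A, C, G, T and a gap channel for read
#' deletions); insertions do not create columns.
#'
#' @param alignments alignment `data.table` (with `seq` and `cigar`).
#' @param ref a `ReferenceGenome`.
#' @param region list or vector `(chrom, start, end)` with 0-based
#'   half-open coordinates; default spans the whole chromosome.
#' @return `data.table`: `chrom`, `pos` (0-based), `ref`, `A`, `C`, `G`,
#'   `T`, `gap`, `depth` (sum of the five channels).
#' @export
pileup <- function(alignments, ref, region = NULL) {
  if (is.null(region)) {
    assert_that(length(ref$chromosomes) == 1L,
                "region required for a multi-chromosome reference")
    region <- list(chrom = names(ref$chromosomes)[1], start = 0L,
                   end = nchar(ref$chromosomes[[1]]))
  }
  region <- as.list(region)
  names(region)[1:3] <- c("chrom", "start", "end")
  region$start <- as.integer(region$start); region$end <- as.integer(region$end)
  assert_that(region$chrom %in% names(ref$chromosomes),
              "region on unknown chromosome '%s'", region$chrom)
  L <- nchar(ref$chromosomes[[region$chrom]])
  assert_that(region$start >= 0 && region$end <= L && region$start < region$end,
              "region outside reference")
  counts <- base_count_matrices(
    alignments[alignments$chrom == region$chrom &
                 alignments$start < region$end &
                 alignments$end > region$start],
    ref)[[region$chrom]]
  idx <- (region$start + 1L):region$end
  refb <- seq_chars(ref$chromosomes[[region$chrom]])[idx]
  data.table::data.table(
    chrom = region$chrom, pos = idx - 1L, ref = refb,
    A = counts[1L, idx], C = counts[2L, idx], G = counts[3L, idx],
    T = counts[4L, idx], gap = counts[5L, idx],
    depth = colSums(counts[, idx, drop = FALSE]))
}

#' Filtered single-nucleotide variant calls from pileup columns
#'
#' A non-reference allele is called iff the column depth is at least
#' `min_cov`, the allele is seen in at least `min_alt_reads` reads, and its
#' frequency (count / depth) is at least `min_freq`. Several qualifying
#' alleles at one column yield several calls.
#'
#' @param columns pileup `data.table` from [pileup()].
#' @param min_cov minimum column depth.
#' @param min_alt_reads minimum reads carrying the variant.
#' @param min_freq minimum variant frequency.
#' @return `data.table`: `chrom`, `pos`, `ref`, `alt`, `alt_count`,
#'   `depth`, `frequency`.
#' @export
call_variants <- function(columns, min_cov = 5L, min_alt_reads = 2L,
                          min_freq = 0.15) {
  out <- list()
  bases <- c("A", "C", "G", "T")
  for (b in bases) {
    cnt <- columns[[b]]
    ok <- columns$depth >= min_cov & columns$ref != b &
      cnt >= min_alt_reads & cnt / columns$depth >= min_freq
    if (any(ok)) {
      out[[b]] <- data.table::data.table(
        chrom = columns$chrom[ok], pos = columns$pos[ok],
        ref = columns$ref[ok], alt = b, alt_count = cnt[ok],
        depth = columns$depth[ok], frequency = cnt[ok] / columns$depth[ok])
    }
  }
  if (!length(out))
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  ref = character(), alt = character(),
                                  alt_count = integer(), depth = integer(),
                                  frequency = numeric()))
  res <- data.table::rbindlist(out)
  data.table::setorderv(res, c("chrom", "pos", "alt"))
  res
}

#' Write variant calls as a VCF-like TSV (1-based positions)
#' @param variants output of [call_variants()].
#' @param path output file.
#' @export
write_variants <- function(variants, path) {
  out <- data.table::data.table(CHROM = variants$chrom,
                                POS = variants$pos + 1L,
                                REF = variants$ref, ALT = variants$alt,
                                DP = variants$depth, AD = variants$alt_count,
                                AF = round(variants$frequency, 4))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
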