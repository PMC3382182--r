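# Masked multi-genome similarity and report glue. Consensuses are
# reference-projected (see consensus_sequences), so the three-way alignment
# is columnwise by construction; no multiple aligner is re-run.

#' Columnwise three-way alignment of reference-projected consensuses
#'
#' @param ref_seq reference chromosome sequence.
#' @param cons_a,cons_b consensus sequences in reference coordinates
#'   (same length as `ref_seq`).
#' @return a `ThreeWayAlignment`: list of three equal-length sequences.
#' @export
anchored_align <- function(ref_seq, cons_a, cons_b) {
  assert_that(nchar(ref_seq) == nchar(cons_a) &&
                nchar(ref_seq) == nchar(cons_b),
              "sequence lengths differ: %d / %d / %d",
              nchar(ref_seq), nchar(cons_a), nchar(cons_b))
  structure(list(ref = ref_seq, a = cons_a, b = cons_b),
            class = "ThreeWayAlignment")
}

#' Mask alignment columns with insufficient coverage in either sample
#'
#' A reference column is retained iff both samples reach `min_depth` there.
#'
#' @param alignment a [anchored_align()] result.
#' @param depth_a,depth_b per-base read depth of samples A and B, in
#'   reference coordinates.
#' @param min_depth minimum depth required in both samples.
#' @return a `MaskedAlignment`: list with `columns` (`data.table`: `pos`
#'   1-based, `ref`, `a`, `b`), `regions` (retained intervals, 0-based
#'   half-open), `retained` (logical vector).
#' @export
mask_low_coverage <- function(alignment, depth_a, depth_b, min_depth = 10L) {
  L <- nchar(alignment$ref)
  assert_that(length(depth_a) == L && length(depth_b) == L,
              "depth array length does not match alignment (%d)", L)
  retained <- depth_a >= min_depth & depth_b >= min_depth
  pos <- which(retained)
  chars <- function(s) seq_chars(s)[pos]
  regions <- if (length(pos)) {
    r <- IRanges::reduce(IRanges::IRanges(pos, pos))
    data.table::data.table(start = IRanges::start(r) - 1L,
                           end = IRanges::end(r))
  } else data.table::data.table(start = integer(), end = integer())
  structure(list(columns = data.table::data.table(
    pos = pos, ref = chars(alignment$ref), a = chars(alignment$a),
    b = chars(alignment$b)),
    regions = regions, retained = retained),
    class = "MaskedAlignment")
}

# Columns (1-based positions) lying inside any CDS feature of a chromosome.
cds_positions <- function(ref, chrom) {
  f <- ref$features[ref$features$chrom == chrom & ref$features$type == "CDS"]
  if (nrow(f) == 0L) return(integer(0))
  unlist(lapply(seq_len(nrow(f)), function(i) (f$start[i] + 1L):f$end[i]))
}

#' Three-way and pairwise identity over masked alignments
#'
#' Percent identical sites across all three sequences and for each pair,
#' split into CDS and non-CDS columns using the reference annotation.
#' Totals are length-weighted means of the per-chromosome values.
#'
#' @param masked named list (by chromosome) of [mask_low_coverage()]
#'   results.
#' @param ref the `ReferenceGenome` providing CDS annotation.
#' @return an `IdentityReport` `data.table` with one row per chromosome
#'   plus a `total` row.
#' @export
identity_report <- function(masked, ref) {
  assert_that(length(masked) > 0 &&
                any(vapply(masked, function(m) nrow(m$columns) > 0, TRUE)),
              "empty masked alignment")
  pct <- function(x) if (length(x)) 100 * mean(x) else NA_real_
  rows <- lapply(names(masked), function(cid) {
    cols <- masked[[cid]]$columns
    in_cds <- cols$pos %in% cds_positions(ref, cid)
    all3 <- cols$ref == cols$a & cols$ref == cols$b
    data.table::data.table(
      chrom = cid, length = nrow(cols),
      cds_length = sum(in_cds), noncds_length = sum(!in_cds),
      pct_identical = pct(all3),
      pct_identical_cds = pct(all3[in_cds]),
      pct_identical_noncds = pct(all3[!in_cds]),
      pct_ref_a = pct(cols$ref == cols$a),
      pct_ref_b = pct(cols$ref == cols$b),
      pct_a_b = pct(cols$a == cols$b))
  })
  per <- data.table::rbindlist(rows)
  wmean <- function(v, w) {
    ok <- !is.na(v) & w > 0
    if (!any(ok)) NA_real_ else sum(v[ok] * w[ok]) / sum(w[ok])
  }
  total <- data.table::data.table(
    chrom = "total", length = sum(per$length),
    cds_length = sum(per$cds_length), noncds_length = sum(per$noncds_length),
    pct_identical = wmean(per$pct_identical, per$length),
    pct_identical_cds = wmean(per$pct_identical_cds, per$cds_length),
    pct_identical_noncds = wmean(per$pct_identical_noncds,
                                 per$noncds_length),
    pct_ref_a = wmean(per$pct_ref_a, per$length),
    pct_ref_b = wmean(per$pct_ref_b, per$length),
    pct_a_b = wmean(per$pct_a_b, per$length))
  out <- data.table::rbindlist(list(per, total))
  data.table::setattr(out, "class", c("IdentityReport", class(out)))
  out
}

#' Gene-panel similarity against assembled contigs
#'
#' Each gene is searched by local nucleotide alignment against every
#' contig; the best contig at or above `min_score` is reported with the
#' percent identity over the aligned region, otherwise the gene is flagged
#' not-found.
#'
#' @param genes named character vector of gene sequences.
#' @param contigs named character vector of contig sequences.
#' @param min_score minimum local alignment score for a gene to count as
#'   found (raw score; stands in for an E-value cutoff).
#' @return a `GenePanelResult` `data.table`: `gene`, `found`,
#'   `best_contig`, `pct_identity`, `aligned_length`, `score`.
#' @export
gene_panel_similarity <- function(genes, contigs, min_score = 100) {
  assert_that(length(genes) > 0, "empty gene panel")
  submat <- nuc_submat()
  rows <- lapply(names(genes), function(g) {
    best <- NULL
    for (ci in names(contigs)) {
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(genes[[g]]),
        Biostrings::DNAString(contigs[[ci]]), type = "local",
        substitutionMatrix = submat, gapOpening = 5, gapExtension = 2)
      sc <- Biostrings::score(pa)
      if (is.null(best) || sc > best$score) {
        p <- seq_chars(as.character(Biostrings::alignedPattern(pa)))
        s <- seq_chars(as.character(Biostrings::alignedSubject(pa)))
        best <- list(contig = ci, score = sc, len = length(p),
                     ident = if (length(p))
                       100 * sum(p == s & p != "-") / length(p) else 0)
      }
    }
    found <- !is.null(best) && best$score >= min_score
    data.table::data.table(
      gene = g, found = found,
      best_contig = if (found) best$contig else NA_character_,
      pct_identity = if (found) best$ident else NA_real_,
      aligned_length = if (found) best$len else NA_integer_,
      score = if (found) best$score else NA_real_)
  })
  out <- data.table::rbindlist(rows)
  data.table::setattr(out, "class", c("GenePanelResult", class(out)))
  out
}

#' Assemble run-level report tables
#'
#' @param reads read `data.table` (`id`, `seq`) of the run.
#' @param profile a `CoverageProfile`.
#' @param identity optional `IdentityReport`.
#' @param n_total_reads total reads sequenced (defaults to `nrow(reads)`),
#'   used for the percent-mapped line.
#' @return list of tables: `read_stats`, `coverage` (per chromosome plus a
#'   totals row), `identity` (when given), `summary`.
#' @export
run_report <- function(reads, profile, identity = NULL,
                       n_total_reads = NULL) {
  if (is.null(reads)) stopf("missing stage output: reads")
  if (is.null(profile)) stopf("missing stage output: coverage profile")
  lens <- nchar(reads$seq)
  read_stats <- data.table::data.table(
    n_reads = nrow(reads), total_bp = sum(lens),
    mean_length = as.integer(round(sum(lens) / max(1L, nrow(reads)))),
    min_length = if (nrow(reads)) min(lens) else NA_integer_,
    max_length = if (nrow(reads)) max(lens) else NA_integer_,
    gc_pct = round(100 * gc_content(paste(reads$seq, collapse = "")), 1))
  cov <- data.table::copy(profile$summary)
  total <- data.table::data.table(
    chrom = "total", category = "", length = sum(cov$length),
    reads = sum(cov$reads), covered_bp = sum(cov$covered_bp),
    coverage_fraction = sum(cov$covered_bp) / sum(cov$length),
    coverage_depth = sum(cov$coverage_depth * cov$length) / sum(cov$length),
    identical_sites_pct = NA_real_, gc = NA_real_)
  cov <- data.table::rbindlist(list(cov, total))
  n_total <- n_total_reads %||% nrow(reads)
  summary <- data.table::data.table(
    metric = c("reads_total", "reads_mapped", "pct_reads_mapped",
               "genome_coverage_pct", "coverage_depth"),
    value = c(n_total, sum(profile$summary$reads),
              round(100 * sum(profile$summary$reads) / n_total, 1),
              round(100 * profile$genome_coverage_fraction, 2),
              round(profile$genome_coverage_depth, 2)))
  list(read_stats = read_stats, coverage = cov, identity = identity,
       summary = summary)
}
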