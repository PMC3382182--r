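# rRNA intron presence/absence genotyping: each read is aligned to an
# intron-bearing and an intron-free variant of the locus; junction-spanning
# reads vote for the variant with the strictly higher alignment score.

#' Build the intron-bearing / intron-free variant pair for a feature
#'
#' Extracts the region around an rRNA feature from the reference (the
#' intron-free allele) and inserts the deterministic intron used by
#' [plant_genotypes()] (the intron-bearing allele).
#'
#' @param ref a `ReferenceGenome`.
#' @param feature_id rRNA feature id (e.g. `"rRNA_SSU"`).
#' @param length intron length (bp).
#' @param flank context kept on each side of the feature (bp).
#' @return list with `with`, `without` (sequences), `junction` (1-based
#'   position of the last exon base before the insertion, in `without`
#'   coordinates), `intron_length`.
#' @export
intron_region_refs <- function(ref, feature_id, length, flank = 400L) {
  frow <- ref$features[ref$features$id == feature_id]
  assert_that(nrow(frow) == 1L, "unknown feature '%s'", feature_id)
  frow <- as.list(frow[1])
  at <- intron_insert_at(frow)
  chrom <- ref$chromosomes[[frow$chrom]]
  from <- max(1L, frow$start + 1L - flank)
  to <- min(nchar(chrom), frow$end + flank)
  without <- substr(chrom, from, to)
  junction <- at - from + 1L
  iseq <- intron_sequence(feature_id, length)
  with <- paste0(substr(without, 1, junction), iseq,
                 substr(without, junction + 1L, nchar(without)))
  list(with = with, without = without, junction = junction,
       intron_length = length)
}

#' Genotype reads for intron presence/absence
#'
#' Each read (tried in both orientations) is aligned to both locus
#' variants. A read is informative only when its alignment spans an
#' exon-intron junction with at least `min_flank` aligned bases on each
#' side; its status is the variant with the strictly higher score.
#'
#' @param reads `data.table` with `id`, `seq`, or a named character vector.
#' @param ref_with intron-bearing variant sequence.
#' @param ref_without intron-free variant sequence.
#' @param min_flank junction support on each side (bp).
#' @return an `IntronCall`: list with `per_read` (`data.table`: `id`,
#'   `status` in `intron+`/`intron-`/`uninformative`, scores) and `summary`
#'   (counts and `fraction_plus` among informative reads).
#' @export
call_introns <- function(reads, ref_with, ref_without, min_flank = 20L) {
  assert_that(!identical(ref_with, ref_without),
              "variant sequences are identical: no intron to genotype")
  ilen <- nchar(ref_with) - nchar(ref_without)
  assert_that(ilen > 0, "ref_with must be longer than ref_without")
  # junction: last matching prefix base
  n <- min(nchar(ref_with), nchar(ref_without))
  wchars <- seq_chars(ref_with)[seq_len(n)]
  ochars <- seq_chars(ref_without)[seq_len(n)]
  first_diff <- which(wchars != ochars)[1]
  junction <- if (is.na(first_diff)) n else first_diff - 1L
  if (is.character(reads))
    reads <- data.table::data.table(id = names(reads), seq = unname(reads))
  submat <- nuc_submat()
  score_and_range <- function(read, refseq) {
    pa <- Biostrings::pairwiseAlignment(Biostrings::DNAString(read),
                                        Biostrings::DNAString(refseq),
                                        type = "global-local",
                                        substitutionMatrix = submat,
                                        gapOpening = 5, gapExtension = 2)
    sub <- Biostrings::subject(pa)
    list(score = Biostrings::score(pa),
         from = IRanges::start(IRanges::ranges(sub)),
         to = IRanges::end(IRanges::ranges(sub)))
  }
  rows <- lapply(seq_len(nrow(reads)), function(i) {
    best <- NULL
    for (orient in c("+", "-")) {
      rs <- if (orient == "+") reads$seq[i] else revcomp(reads$seq[i])
      w <- score_and_range(rs, ref_with)
      o <- score_and_range(rs, ref_without)
      cand <- list(w = w, o = o, top = max(w$score, o$score))
      if (is.null(best) || cand$top > best$top) best <- cand
    }
    spans <- function(r, j) r$from <= j - min_flank + 1L && r$to >= j + min_flank
    informative <- spans(best$o, junction) ||
      spans(best$w, junction) || spans(best$w, junction + ilen)
    status <- "uninformative"
    if (informative && best$w$score != best$o$score)
      status <- if (best$w$score > best$o$score) "intron+" else "intron-"
    data.table::data.table(id = reads$id[i], status = status,
                           score_with = best$w$score,
                           score_without = best$o$score)
  })
  per_read <- data.table::rbindlist(rows)
  n_plus <- sum(per_read$status == "intron+")
  n_minus <- sum(per_read$status == "intron-")
  structure(list(per_read = per_read,
                 summary = list(n_reads = nrow(per_read),
                                n_informative = n_plus + n_minus,
                                n_plus = n_plus, n_minus = n_minus,
                                fraction_plus =
                                  if (n_plus + n_minus > 0)
                                    n_plus / (n_plus + n_minus)
                                  else NA_real_)),
            class = "IntronCall")
}

#' @export
print.IntronCall <- function(x, ...) {
  s <- x$summary
  cat(sprintf("IntronCall: %d/%d informative reads intron+ (%.0f%%)\n",
              s$n_plus, s$n_informative,
              100 * (s$fraction_plus %||% NA_real_)))
  invisible(x)
}
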