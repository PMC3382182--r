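#' Quality-trim reads and drop ambiguous ones
#'
#' Removes the maximal prefix and suffix whose per-base error probability
#' (Phred+33) exceeds `error_prob_threshold`, then drops reads whose
#' retained body contains ambiguity codes (anything outside ACGT) or is
#' empty.
#'
#' @param reads `data.table` with `id`, `seq`, `qual`.
#' @param error_prob_threshold error probability above which terminal bases
#'   are trimmed.
#' @return list with `reads` (trimmed table) and `dropped` (ids of removed
#'   reads).
#' @export
trim_reads <- function(reads, error_prob_threshold = 0.01) {
  reads <- data.table::as.data.table(reads)
  assert_that(all(c("id", "seq", "qual") %in% names(reads)),
              "reads need id/seq/qual columns")
  bad <- which(nchar(reads$seq) != nchar(reads$qual))
  if (length(bad))
    stopf("malformed FASTQ record at index %d: seq/qual length mismatch",
          bad[1])
  n <- nrow(reads)
  out_seq <- character(n); out_qual <- character(n); keep <- logical(n)
  for (i in seq_len(n)) {
    p <- 10^(-(utf8ToInt(reads$qual[i]) - 33L) / 10)
    ok <- p <= error_prob_threshold
    if (!any(ok)) next
    from <- which(ok)[1]
    to <- which(ok)[sum(ok)]
    body <- substr(reads$seq[i], from, to)
    if (grepl("[^ACGT]", body)) next
    out_seq[i] <- body
    out_qual[i] <- substr(reads$qual[i], from, to)
    keep[i] <- TRUE
  }
  list(reads = data.table::data.table(id = reads$id[keep],
                                      seq = out_seq[keep],
                                      qual = out_qual[keep]),
       dropped = reads$id[!keep])
}
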