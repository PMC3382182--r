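# Six-frame translated search of nucleotide queries against the protein
# database: amino-acid k-mer seeding plus Smith-Waterman extension with
# BLOSUM62 (gap open 11 / extend 1). A small stand-in for a full translated
# search engine; pre-computed tabular hits can be imported instead.

# Translate one frame via a cached codon lookup; stop codons become '*',
# ambiguous codons 'X', trailing partial codon dropped. Returns "" for
# frames shorter than one codon.
translate_frame <- local({
  code <- NULL
  function(dna, frame) {
    if (is.null(code)) code <<- Biostrings::GENETIC_CODE
    s <- if (frame > 0) dna else revcomp(dna)
    f <- abs(frame)
    L <- nchar(s)
    n_codon <- (L - f + 1L) %/% 3L
    if (n_codon < 1L) return("")
    starts <- f + 3L * (seq_len(n_codon) - 1L)
    aa <- code[substring(s, starts, starts + 2L)]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }
})

#' Build an amino-acid k-mer seed index for a protein database
#' @param db a `ProteinDB`.
#' @param k seed length (amino acids).
#' @return a keyed `data.table` used by [translated_search()].
#' @export
protein_kmer_index <- function(db, k = 5L) {
  pr <- db$proteins
  rows <- lapply(seq_len(nrow(pr)), function(i) {
    L <- nchar(pr$seq[i])
    if (L < k) return(NULL)
    off <- seq_len(L - k + 1L)
    data.table::data.table(kmer = substring(pr$seq[i], off, off + k - 1L),
                           protein = i)
  })
  idx <- unique(data.table::rbindlist(rows))
  data.table::setkey(idx, kmer)
  data.table::setattr(idx, "k", k)
  idx
}

# Convert an aa interval in frame coordinates to 1-based forward-strand
# nucleotide coordinates on the query.
frame_aa_to_nt <- function(aa_start, aa_end, frame, qlen) {
  f <- abs(frame)
  nt_start <- f + 3L * (aa_start - 1L)
  nt_end <- f + 3L * aa_end - 1L
  if (frame > 0) c(nt_start, nt_end)
  else c(qlen - nt_end + 1L, qlen - nt_start + 1L)
}

#' Six-frame translated search against a protein database
#'
#' @param query_dna a single DNA sequence (character).
#' @param db a `ProteinDB`.
#' @param min_score minimum raw alignment score to report.
#' @param index optional pre-built [protein_kmer_index()] (rebuilt per call
#'   otherwise).
#' @param query_id id recorded in the hit table.
#' @return `data.table` of local hits: `query_id`, `subject_id`, `frame`,
#'   `qstart`/`qend` (1-based forward-strand nucleotides), `sstart`/`send`,
#'   `matches`, `cols` (aligned columns), `score`.
#' @export
translated_search <- function(query_dna, db, min_score = 35, index = NULL,
                              query_id = "query") {
  assert_that(nchar(query_dna) >= 3, "query shorter than one codon")
  if (is.null(index)) index <- protein_kmer_index(db)
  k <- attr(index, "k")
  qlen <- nchar(query_dna)
  pr <- db$proteins
  out <- list()
  for (frame in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    aa <- translate_frame(query_dna, frame)
    La <- nchar(aa)
    if (La < k) next
    off <- seq_len(La - k + 1L)
    kmers <- unique(substring(aa, off, off + k - 1L))
    cand <- index[data.table::data.table(kmer = kmers), nomatch = NULL]
    cand <- unique(cand$protein)
    if (!length(cand)) next
    # one vectorised call: candidate proteins as patterns vs the frame
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(pr$seq[cand]), Biostrings::AAString(aa),
      type = "local", substitutionMatrix = blosum62(),
      gapOpening = 11, gapExtension = 1)
    sc <- Biostrings::score(pa)
    keep <- which(sc >= min_score)
    if (!length(keep)) next
    nm <- Biostrings::nmatch(pa)
    nc <- Biostrings::nchar(pa)
    s_rng <- IRanges::ranges(Biostrings::pattern(pa))
    q_rng <- IRanges::ranges(Biostrings::subject(pa))
    qa_start <- IRanges::start(q_rng)[keep]
    qa_end <- IRanges::end(q_rng)[keep]
    nt <- vapply(seq_along(keep), function(j)
      frame_aa_to_nt(qa_start[j], qa_end[j], frame, qlen), integer(2))
    out[[length(out) + 1L]] <- data.table::data.table(
      query_id = query_id, subject_id = pr$id[cand[keep]],
      frame = frame, qstart = nt[1, ], qend = nt[2, ],
      sstart = IRanges::start(s_rng)[keep], send = IRanges::end(s_rng)[keep],
      matches = nm[keep], cols = nc[keep], score = sc[keep])
  }
  if (length(out)) data.table::rbindlist(out) else empty_hits()
}

empty_hits <- function() {
  data.table::data.table(query_id = character(), subject_id = character(),
                         frame = integer(), qstart = integer(),
                         qend = integer(), sstart = integer(),
                         send = integer(), matches = integer(),
                         cols = integer(), score = numeric())
}

#' Import pre-computed translated-search hits (12-column tabular dialect)
#'
#' Columns: qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore. Matches are recomputed as
#' `round(pident/100 * length)`; the bitscore is used as the hit score.
#'
#' @param x path to a tabular hit file, or a `data.frame` with those 12
#'   columns.
#' @return hit `data.table` compatible with [merge_hits()].
#' @export
import_tabular_hits <- function(x) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  tab <- if (is.character(x)) data.table::fread(x, header = FALSE)
  else data.table::as.data.table(x)
  assert_that(ncol(tab) == 12L, "expected 12 tabular columns, got %d",
              ncol(tab))
  data.table::setnames(tab, cols)
  qs <- pmin(tab$qstart, tab$qend)
  qe <- pmax(tab$qstart, tab$qend)
  data.table::data.table(
    query_id = as.character(tab$qseqid), subject_id = as.character(tab$sseqid),
    frame = ifelse(tab$qstart <= tab$qend, 1L, -1L),
    qstart = qs, qend = qe, sstart = tab$sstart, send = tab$send,
    matches = as.integer(round(tab$pident / 100 * tab$length)),
    cols = as.integer(tab$length), score = tab$bitscore)
}

#' Nucleotide screen of contigs against an rRNA reference set
#'
#' Local alignment of each contig against each rRNA reference; only hits
#' with aligned length above `min_hit_len` are retained.
#'
#' @param contigs named character vector of contig sequences.
#' @param rrna_refs named character vector of rRNA reference sequences.
#' @param min_hit_len minimum aligned length (bp), exclusive.
#' @param min_identity minimum identity of a reported hit.
#' @return `data.table`: `contig`, `rrna`, `length`, `identity`, `score`.
#' @export
screen_rrna <- function(contigs, rrna_refs, min_hit_len = 200,
                        min_identity = 0.8) {
  out <- list()
  submat <- nuc_submat()
  for (ci in names(contigs)) {
    for (ri in names(rrna_refs)) {
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(contigs[[ci]]),
        Biostrings::DNAString(rrna_refs[[ri]]),
        type = "local", substitutionMatrix = submat,
        gapOpening = 5, gapExtension = 2)
      p <- seq_chars(as.character(Biostrings::alignedPattern(pa)))
      s <- seq_chars(as.character(Biostrings::alignedSubject(pa)))
      len <- length(p)
      if (len <= min_hit_len) next
      ident <- sum(p == s & p != "-") / len
      if (ident < min_identity) next
      out[[length(out) + 1L]] <- data.table::data.table(
        contig = ci, rrna = ri, length = len, identity = ident,
        score = Biostrings::score(pa))
    }
  }
  if (length(out)) data.table::rbindlist(out)
  else data.table::data.table(contig = character(), rrna = character(),
                              length = integer(), identity = numeric(),
                              score = numeric())
}
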