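# Greedy seed-and-extend read mapper: exact k-mer seeds (k = 14 by default)
# voted by diagonal, followed by banded global-local extension with affine
# gaps. One best location per read; ties broken by lowest (chrom, position).

cigar_ops <- function(cigar) {
  len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  op <- regmatches(cigar, gregexpr("[A-Z]", cigar))[[1]]
  list(op = op, len = len)
}

# Map a CIGAR + alignment start to (ref position, read position) pairs for
# M columns, plus deleted reference positions. Positions 0-based.
cigar_pairs <- function(cigar, start) {
  ops <- cigar_ops(cigar)
  rpos <- start
  qpos <- 0L
  ref <- integer(0); qry <- integer(0); del <- integer(0)
  ins <- integer(0)
  for (i in seq_along(ops$op)) {
    n <- ops$len[i]
    switch(ops$op[i],
           M = {
             ref <- c(ref, rpos + seq_len(n) - 1L)
             qry <- c(qry, qpos + seq_len(n) - 1L)
             rpos <- rpos + n; qpos <- qpos + n
           },
           D = { del <- c(del, rpos + seq_len(n) - 1L); rpos <- rpos + n },
           I = { ins <- c(ins, rpos); qpos <- qpos + n },
           S = { qpos <- qpos + n },
           stopf("unsupported CIGAR op '%s'", ops$op[i]))
  }
  list(ref = ref, qry = qry, del = del, ins = ins)
}

# Build a CIGAR from gapped pattern/subject alignment strings.
cigar_from_gapped <- function(p, s) {
  pc <- seq_chars(p); sc <- seq_chars(s)
  op <- ifelse(pc == "-", "D", ifelse(sc == "-", "I", "M"))
  r <- rle(op)
  paste0(r$lengths, r$values, collapse = "")
}

nuc_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                           baseOnly = FALSE)
}

# Ungapped comparison at the voted diagonal: the common case under a
# substitution-only error model. Returns NULL when the read does not fit or
# identity is below threshold (caller falls back to banded DP).
ungapped_alignment <- function(read_seq, chrom_seq, chrom, diag, strand,
                               read_id, min_identity, min_match_len) {
  L <- nchar(read_seq)
  if (diag < 1L || diag + L - 1L > nchar(chrom_seq)) return(NULL)
  rc <- seq_chars(read_seq)
  cc <- seq_chars(substr(chrom_seq, diag, diag + L - 1L))
  mism <- sum(rc != cc)
  identity <- 1 - mism / L
  if (identity < min_identity || L < min_match_len) return(NULL)
  data.table::data.table(
    read_id = read_id, chrom = chrom, start = diag - 1L,
    end = diag - 1L + L, strand = strand, cigar = paste0(L, "M"),
    seq = read_seq, mismatches = mism, alen = L, identity = identity,
    score = 2 * (L - mism) - 3 * mism)
}

# Extend one read against a reference window; returns NULL or an alignment
# row (start 0-based within the window's chromosome).
extend_alignment <- function(read_seq, chrom_seq, chrom, window_start,
                             window_end, strand, read_id,
                             min_identity, min_match_len, submat) {
  win <- substr(chrom_seq, window_start, window_end)
  pa <- Biostrings::pairwiseAlignment(read_seq, win, type = "global-local",
                                      substitutionMatrix = submat,
                                      gapOpening = 5, gapExtension = 2)
  p <- as.character(Biostrings::alignedPattern(pa))
  s <- as.character(Biostrings::alignedSubject(pa))
  cols <- nchar(p)
  if (cols == 0L) return(NULL)
  pc <- seq_chars(p); sc <- seq_chars(s)
  matches <- sum(pc == sc & pc != "-")
  identity <- matches / cols
  if (identity < min_identity || cols < min_match_len) return(NULL)
  start0 <- window_start - 1L + Biostrings::start(Biostrings::subject(pa)) - 1L
  cigar <- cigar_from_gapped(p, s)
  data.table::data.table(
    read_id = read_id, chrom = chrom, start = start0,
    end = start0 + cigar_ref_span(cigar), strand = strand, cigar = cigar,
    seq = read_seq, mismatches = sum(pc != sc & pc != "-" & sc != "-"),
    alen = cols, identity = identity,
    score = Biostrings::score(pa))
}

#' Map reads against a reference genome
#'
#' @param reads `data.table` with `id`, `seq` (qualities optional) or a
#'   character vector of sequences named by read id.
#' @param ref a [reference_genome()].
#' @param min_identity minimum alignment identity (matches / aligned
#'   columns) to report.
#' @param min_match_len minimum aligned length (columns).
#' @param k seed k-mer size.
#' @param seed_step spacing between seed k-mers along a read.
#' @return list with `alignments` (`data.table`: `read_id`, `chrom`,
#'   `start`, `end` 0-based half-open, `strand`, `cigar`, `seq` in reference
#'   orientation, `mismatches`, `alen`, `identity`, `score`) and `unmapped`
#'   (read ids).
#' @export
map_reads <- function(reads, ref, min_identity = 0.90, min_match_len = 40,
                      k = 14L, seed_step = 60L) {
  assert_that(length(ref$chromosomes) > 0 && sum(nchar(ref$chromosomes)) > 0,
              "empty reference")
  if (is.character(reads))
    reads <- data.table::data.table(id = names(reads), seq = unname(reads))
  reads <- data.table::as.data.table(reads)
  if (nrow(reads) == 0L)
    return(list(alignments = empty_alignments(), unmapped = character(0)))

  rc_all <- revcomp(reads$seq)

  # seed table over both orientations
  seed_list <- vector("list", 2L * nrow(reads))
  for (i in seq_len(nrow(reads))) {
    for (orient in c("+", "-")) {
      s <- if (orient == "+") reads$seq[i] else rc_all[i]
      L <- nchar(s)
      if (L < k) next
      offs <- unique(c(seq(1L, L - k + 1L, by = seed_step), L - k + 1L))
      kmers <- substring(s, offs, offs + k - 1L)
      keep <- !grepl("[^ACGT]", kmers)
      if (!any(keep)) next
      seed_list[[2L * i - (orient == "+")]] <- data.table::data.table(
        read_idx = i, orient = orient, offset = offs[keep],
        kmer = kmers[keep])
    }
  }
  seeds <- data.table::rbindlist(seed_list)
  if (nrow(seeds) == 0L)
    return(list(alignments = empty_alignments(), unmapped = reads$id))

  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds$kmer))
  votes <- list()
  for (cid in names(ref$chromosomes)) {
    m <- Biostrings::matchPDict(pd, Biostrings::DNAString(ref$chromosomes[[cid]]))
    sidx <- Biostrings::startIndex(m)
    counts <- lengths(sidx)
    hit_idx <- rep(seq_along(counts), counts)
    if (!length(hit_idx)) next
    starts <- unlist(sidx, use.names = FALSE)
    # diag = 1-based alignment start implied by the seed
    votes[[cid]] <- data.table::data.table(
      read_idx = seeds$read_idx[hit_idx], orient = seeds$orient[hit_idx],
      chrom = cid, diag = starts - seeds$offset[hit_idx] + 1L)
  }
  votes <- data.table::rbindlist(votes)
  submat <- nuc_submat()
  aligned <- list()
  if (nrow(votes)) {
    tally <- votes[, list(n = .N), by = c("read_idx", "orient", "chrom",
                                          "diag")]
    data.table::setorderv(tally, c("read_idx", "n", "chrom", "diag"),
                          c(1L, -1L, 1L, 1L))
    best <- tally[, utils::head(.SD, 3L), by = "read_idx"]
    cand_by_read <- split(best, best$read_idx)
    for (cand in cand_by_read) {
      ri <- cand$read_idx[1]
      # candidates in vote order; first acceptable alignment wins
      # (equal-vote ties are pre-sorted by lowest (chrom, position))
      for (j in seq_len(nrow(cand))) {
        orient <- cand$orient[j]
        rseq <- if (orient == "+") reads$seq[ri] else rc_all[ri]
        L <- nchar(rseq)
        cseq <- ref$chromosomes[[cand$chrom[j]]]
        al <- ungapped_alignment(rseq, cseq, cand$chrom[j], cand$diag[j],
                                 orient, reads$id[ri], min_identity,
                                 min_match_len)
        if (is.null(al)) {
          ws <- max(1L, cand$diag[j] - 15L)
          we <- min(nchar(cseq), cand$diag[j] + L + 15L)
          al <- extend_alignment(rseq, cseq, cand$chrom[j], ws, we, orient,
                                 reads$id[ri], min_identity, min_match_len,
                                 submat)
        }
        if (!is.null(al)) {
          aligned[[length(aligned) + 1L]] <- al
          break
        }
      }
    }
  }
  alignments <- if (length(aligned)) data.table::rbindlist(aligned)
  else empty_alignments()
  list(alignments = alignments,
       unmapped = setdiff(reads$id, alignments$read_id))
}

empty_alignments <- function() {
  data.table::data.table(read_id = character(), chrom = character(),
                         start = integer(), end = integer(),
                         strand = character(), cigar = character(),
                         seq = character(), mismatches = integer(),
                         alen = integer(), identity = numeric(),
                         score = numeric())
}
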