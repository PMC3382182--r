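# File-format helpers. Sequence formats go through Biostrings; tables are
# plain TSV via data.table. SAM text IO is minimal (QNAME..QUAL + NM tag)
# because the in-memory alignment table is the native representation.

#' Write named sequences to FASTA
#' @param seqs named character vector of DNA sequences.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read FASTA into a named character vector
#' @param path input file.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(s), names(s))
}

#' Write a read table to FASTQ
#' @param reads `data.table` with `id`, `seq`, `qual`.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads))
    writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual),
               con)
  invisible(path)
}

#' Read FASTQ into a read table
#' @param path input file.
#' @return `data.table` with `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L)
    return(data.table::data.table(id = character(), seq = character(),
                                  qual = character()))
  if (length(lines) %% 4L != 0L)
    stopf("malformed FASTQ: %d lines is not a multiple of 4", length(lines))
  i <- seq(1L, length(lines), by = 4L)
  bad <- which(substr(lines[i], 1, 1) != "@")
  if (length(bad))
    stopf("malformed FASTQ record at index %d", bad[1])
  data.table::data.table(id = sub("^@", "", sub(" .*", "", lines[i])),
                         seq = lines[i + 1L], qual = lines[i + 3L])
}

#' Export features as GFF3 (1-based closed coordinates)
#' @param ref a `ReferenceGenome`.
#' @param path output file.
#' @export
write_gff3 <- function(ref, path) {
  f <- ref$features
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(f)) {
    writeLines(sprintf("%s\tpicometa\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                       f$chrom, f$type, f$start + 1L, f$end, f$strand, f$id),
               con)
  }
  invisible(path)
}

#' Read a GFF3 file into a feature table (0-based half-open)
#' @param path input file.
#' @return `data.table` with `id`, `chrom`, `start`, `end`, `type`, `strand`.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines))
    return(data.table::data.table(id = character(), chrom = character(),
                                  start = integer(), end = integer(),
                                  type = character(), strand = character()))
  parts <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  data.table::data.table(
    id = sub(".*ID=([^;]+).*", "\\1", parts[[9]]),
    chrom = parts[[1]], start = as.integer(parts[[4]]) - 1L,
    end = as.integer(parts[[5]]), type = parts[[3]], strand = parts[[7]])
}

cigar_ref_span <- function(cigar) {
  ops <- cigar_ops(cigar)
  sum(ops$len[ops$op %in% c("M", "D")])
}

#' Export alignments as SAM text
#' @param alignments alignment `data.table` from [map_reads()].
#' @param ref a `ReferenceGenome` (for header `@SQ` lines).
#' @param path output file.
#' @export
write_sam <- function(alignments, ref, path) {
  con <- file(path, "w")
  on.exit(close(con))
  lens <- chrom_lengths(ref)
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens)), con)
  if (nrow(alignments)) {
    flag <- ifelse(alignments$strand == "-", 16L, 0L)
    writeLines(sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*\tNM:i:%d",
                       alignments$read_id, flag, alignments$chrom,
                       alignments$start + 1L, alignments$cigar,
                       alignments$seq, alignments$mismatches), con)
  }
  invisible(path)
}

#' Import alignments from SAM text
#' @param path input SAM file.
#' @return alignment `data.table` (`read_id`, `chrom`, `start`, `end`,
#'   `strand`, `cigar`, `seq`, `mismatches`).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(data.table::data.table(read_id = character(), chrom = character(),
                                  start = integer(), end = integer(),
                                  strand = character(), cigar = character(),
                                  seq = character(), mismatches = integer()))
  parts <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  nm <- rep(NA_integer_, length(lines))
  nm_hit <- regmatches(lines, regexpr("NM:i:[0-9]+", lines))
  has_nm <- grepl("NM:i:", lines, fixed = TRUE)
  nm[has_nm] <- as.integer(sub("NM:i:", "", nm_hit, fixed = TRUE))
  start <- as.integer(parts[[4]]) - 1L
  cigar <- parts[[6]]
  data.table::data.table(
    read_id = parts[[1]], chrom = parts[[3]], start = start,
    end = start + vapply(cigar, cigar_ref_span, 0L, USE.NAMES = FALSE),
    strand = ifelse(bitwAnd(as.integer(parts[[2]]), 16L) > 0L, "-", "+"),
    cigar = cigar, seq = parts[[10]], mismatches = nm)
}

#' Write a protein database to FASTA + taxonomy/groups TSV
#' @param db a `ProteinDB`.
#' @param fasta,taxonomy,groups output paths (`NULL` to skip).
#' @export
write_protein_db <- function(db, fasta, taxonomy = NULL, groups = NULL) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(stats::setNames(db$proteins$seq,
                                            db$proteins$id)), fasta)
  if (!is.null(taxonomy))
    data.table::fwrite(db$taxonomy, taxonomy, sep = "\t")
  if (!is.null(groups))
    data.table::fwrite(db$proteins[, c("id", "group")], groups, sep = "\t")
  invisible(fasta)
}

#' Read a protein database from FASTA + taxonomy TSV (+ optional groups)
#' @param fasta protein FASTA; ids formatted `genome|anything`.
#' @param taxonomy TSV with columns `genome`, `genus`, `class`.
#' @param groups optional TSV with columns `id`, `group`.
#' @return a `ProteinDB`.
#' @export
read_protein_db <- function(fasta, taxonomy, groups = NULL) {
  s <- Biostrings::readAAStringSet(fasta)
  tax <- data.table::fread(taxonomy)
  pr <- data.table::data.table(id = names(s),
                               genome = sub("\\|.*", "", names(s)),
                               seq = as.character(s))
  pr <- merge(pr, tax, by = "genome", sort = FALSE)
  if (!is.null(groups)) {
    pr <- merge(pr, data.table::fread(groups), by = "id", sort = FALSE)
  }
  protein_db(pr)
}
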