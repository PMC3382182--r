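# Ortholog-derived identity/length threshold matrix. Thresholds come from
# end-gap-free global (overlap) alignments of each protein against its
# ortholog-group members: internal gaps count as mismatch columns, end gaps
# are excluded from the denominator. Genes present in a single genome are
# flagged SPECIFIC and fall back to the 80% / 50 aa default.

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' End-gap-free global alignment identity between two proteins
#'
#' @param a,b amino-acid sequences (character).
#' @return list with `identity` (matching columns / aligned columns,
#'   end gaps excluded, internal gaps counted as mismatches) and `length`
#'   (aligned columns).
#' @export
protein_pair_identity <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(Biostrings::AAString(a),
                                      Biostrings::AAString(b),
                                      type = "overlap",
                                      substitutionMatrix = blosum62(),
                                      gapOpening = 10, gapExtension = 0.5)
  p <- seq_chars(as.character(Biostrings::alignedPattern(pa)))
  s <- seq_chars(as.character(Biostrings::alignedSubject(pa)))
  cols <- length(p)
  if (cols == 0L) return(list(identity = 0, length = 0L))
  list(identity = sum(p == s & p != "-") / cols, length = cols)
}

#' Build the per-protein assignment threshold matrix
#'
#' For each protein with orthologs, the minimum identity `I_min` and the
#' minimum alignment length `L_min` are taken over its pairwise alignments
#' against ortholog-group members of other genomes, once restricted to the
#' protein's genus and once to its class. Proteins whose group spans a
#' single genome get the SPECIFIC flag with defaults (0.80, 50 aa).
#'
#' @param db a `ProteinDB` with ortholog groups in the `group` column.
#' @param default_identity,default_length defaults for SPECIFIC genes.
#' @return a `ThresholdMatrix` `data.table` with one row per protein:
#'   `protein_id`, `specific`, `i_min_genus`, `l_min_genus`, `i_min_class`,
#'   `l_min_class`.
#' @export
build_threshold_matrix <- function(db, default_identity = 0.80,
                                   default_length = 50L) {
  assert_that(inherits(db, "ProteinDB") && nrow(db$proteins) > 0,
              "empty protein database")
  pr <- db$proteins
  # pairwise alignments computed once per unordered in-group pair
  pair_cache <- new.env(parent = emptyenv())
  pair_stats <- function(i, j) {
    key <- paste(sort(c(pr$id[i], pr$id[j])), collapse = "\r")
    got <- pair_cache[[key]]
    if (is.null(got)) {
      got <- protein_pair_identity(pr$seq[i], pr$seq[j])
      pair_cache[[key]] <- got
    }
    got
  }
  rows <- lapply(seq_len(nrow(pr)), function(i) {
    grp <- pr$group[i]
    mates <- which(!is.na(grp) & pr$group == grp &
                     pr$genome != pr$genome[i])
    if (!length(mates)) {
      return(data.table::data.table(
        protein_id = pr$id[i], specific = TRUE,
        i_min_genus = default_identity, l_min_genus = default_length,
        i_min_class = default_identity, l_min_class = default_length))
    }
    st <- lapply(mates, pair_stats, i = i)
    ident <- vapply(st, `[[`, 0, "identity")
    len <- vapply(st, `[[`, 0L, "length")
    in_genus <- pr$genus[mates] == pr$genus[i]
    in_class <- pr$class[mates] == pr$class[i]
    data.table::data.table(
      protein_id = pr$id[i], specific = FALSE,
      i_min_genus = if (any(in_genus)) min(ident[in_genus]) else NA_real_,
      l_min_genus = if (any(in_genus)) min(len[in_genus]) else NA_integer_,
      i_min_class = if (any(in_class)) min(ident[in_class]) else NA_real_,
      l_min_class = if (any(in_class)) min(len[in_class]) else NA_integer_)
  })
  out <- data.table::rbindlist(rows)
  data.table::setattr(out, "class",
                      c("ThresholdMatrix", class(out)))
  out
}
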