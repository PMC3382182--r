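# Hierarchical genus -> class -> default assignment against the threshold
# matrix, plus batch classification of contigs/fragments.

#' Assign one query from its merged alignments
#'
#' The Best Hit is the subject with the highest merged score (ties broken
#' by lowest subject id). The query is assigned to the subject's genus if
#' both genus thresholds are met, else to its class if both class
#' thresholds are met, else to the Best Hit's genus under the default
#' 80% / 50 aa rule, else left unassigned.
#'
#' @param merged merged-alignment `data.table` for one query
#'   (see [merge_hits()]); may be empty.
#' @param matrix a `ThresholdMatrix` covering the database proteins.
#' @param db the `ProteinDB`.
#' @param default_identity,default_length fallback thresholds.
#' @return one-row `data.table`: `query_id`, `level` (`genus`, `class`,
#'   `bbh-default`, `unassigned`), `taxon`, `subject_id`, `I`, `L`.
#' @export
assign_taxon <- function(merged, matrix, db, default_identity = 0.80,
                         default_length = 50L) {
  if (nrow(merged) == 0L)
    return(data.table::data.table(query_id = NA_character_,
                                  level = "unassigned", taxon = NA_character_,
                                  subject_id = NA_character_, I = NA_real_,
                                  L = NA_integer_))
  o <- order(-merged$score, merged$subject_id)
  bbh <- merged[o[1]]
  row <- matrix[matrix$protein_id == bbh$subject_id]
  assert_that(nrow(row) == 1L, "threshold matrix misses protein '%s'",
              bbh$subject_id)
  prot <- db$proteins[db$proteins$id == bbh$subject_id]
  lvl <- "unassigned"; taxon <- NA_character_
  if (!row$specific && !is.na(row$i_min_genus) &&
      bbh$I >= row$i_min_genus && bbh$L >= row$l_min_genus) {
    lvl <- "genus"; taxon <- prot$genus
  } else if (!row$specific && !is.na(row$i_min_class) &&
             bbh$I >= row$i_min_class && bbh$L >= row$l_min_class) {
    lvl <- "class"; taxon <- prot$class
  } else if (bbh$I >= default_identity && bbh$L >= default_length) {
    lvl <- "bbh-default"; taxon <- prot$genus
  }
  data.table::data.table(query_id = bbh$query_id, level = lvl, taxon = taxon,
                         subject_id = bbh$subject_id, I = bbh$I, L = bbh$L)
}

#' Classify a set of nucleotide queries against a protein database
#'
#' Runs the translated search, merges hits per subject, and applies
#' [assign_taxon()] to each query.
#'
#' @param queries named character vector of DNA sequences.
#' @param db a `ProteinDB`.
#' @param matrix a `ThresholdMatrix` (built from `db` when `NULL`).
#' @param min_score minimum raw hit score.
#' @param index optional pre-built [protein_kmer_index()].
#' @return `data.table` with one assignment row per query (queries without
#'   hits are `unassigned` with `NA` evidence), plus a `bbh_taxon` column
#'   carrying the raw Best Hit genus for comparison.
#' @export
classify_queries <- function(queries, db, matrix = NULL, min_score = 35,
                             index = NULL) {
  if (is.null(matrix)) matrix <- build_threshold_matrix(db)
  if (is.null(index)) index <- protein_kmer_index(db)
  rows <- lapply(names(queries), function(qid) {
    hits <- translated_search(queries[[qid]], db, min_score = min_score,
                              index = index, query_id = qid)
    merged <- merge_hits_by_subject(hits)
    a <- assign_taxon(merged, matrix, db)
    a$query_id <- qid
    a$bbh_taxon <- if (nrow(merged)) {
      o <- order(-merged$score, merged$subject_id)
      db$proteins$genus[db$proteins$id == merged$subject_id[o[1]]]
    } else NA_character_
    a
  })
  data.table::rbindlist(rows)
}

#' Leave-one-out false-positive validation of the classifier
#'
#' Removes one genome from the database, samples random fragments from its
#' nuclear DNA, classifies them, and reports the wrong-genus rate for the
#' raw Best Hit (`fp_bbh`) and for the threshold-filtered assignment
#' (`fp_filtered`, counting only genus-level or default-rule assignments to
#' a genus other than the held-out genome's). Class-level assignments are
#' not errors. Denominator: fragments with at least one hit.
#'
#' @param db a `ProteinDB` with `genomes_dna` (the held-out genome's DNA
#'   must be available).
#' @param held_out genome label to hold out.
#' @param fragment_len fragment length (bp).
#' @param n_fragments number of fragments.
#' @param seed integer seed.
#' @param keep_in_db control mode: classify against the full database
#'   (self-matches allowed).
#' @param min_score minimum raw hit score.
#' @param matrix,index optional pre-built [build_threshold_matrix()] and
#'   [protein_kmer_index()] for the reduced database (they are identical
#'   across seeds and fragment lengths, so callers can reuse them).
#' @return list with `fp_bbh`, `fp_filtered`, `n_classified`,
#'   `assignments`.
#' @export
validate_false_positives <- function(db, held_out, fragment_len = 500L,
                                     n_fragments = 200L, seed = 1L,
                                     keep_in_db = FALSE, min_score = 35,
                                     matrix = NULL, index = NULL) {
  assert_that(!is.null(db$genomes_dna) && held_out %in% names(db$genomes_dna),
              "no DNA available for genome '%s'", held_out)
  gseq <- db$genomes_dna[[held_out]]$seq
  assert_that(fragment_len <= nchar(gseq),
              "fragment_len exceeds genome length (%d bp)", nchar(gseq))
  true_genus <- db$taxonomy$genus[db$taxonomy$genome == held_out][1]
  use_db <- if (keep_in_db) db else drop_genome(db, held_out)
  if (is.null(matrix)) matrix <- build_threshold_matrix(use_db)
  if (is.null(index)) index <- protein_kmer_index(use_db)
  frags <- with_seed(seed, {
    starts <- sample.int(nchar(gseq) - fragment_len + 1L, n_fragments,
                         replace = TRUE)
    f <- substring(gseq, starts, starts + fragment_len - 1L)
    flip <- sample(c(TRUE, FALSE), n_fragments, replace = TRUE)
    f[flip] <- revcomp(f[flip])
    stats::setNames(f, sprintf("frag_%04d", seq_len(n_fragments)))
  })
  asn <- classify_queries(frags, use_db, matrix, min_score = min_score,
                          index = index)
  hit <- !is.na(asn$bbh_taxon)
  n_cl <- sum(hit)
  fp_bbh <- if (n_cl) mean(asn$bbh_taxon[hit] != true_genus) else NA_real_
  wrong_filtered <- asn$level[hit] %in% c("genus", "bbh-default") &
    asn$taxon[hit] != true_genus
  fp_filtered <- if (n_cl) mean(wrong_filtered) else NA_real_
  list(fp_bbh = fp_bbh, fp_filtered = fp_filtered, n_classified = n_cl,
       assignments = asn)
}
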