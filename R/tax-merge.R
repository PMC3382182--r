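#' Merge local hits of one query-subject pair into a non-redundant
#' global alignment
#'
#' The merged alignment length `L` is the size (in amino acids) of the
#' union of query positions covered by any hit; overlapping positions are
#' counted once and attributed to the higher-scoring hit, whose match
#' density they inherit. `I` is the match total over the union divided by
#' `L`.
#'
#' @param hits hit `data.table` (see [translated_search()]); all rows must
#'   share `query_id` and `subject_id`.
#' @return one-row `data.table`: `query_id`, `subject_id`, `L` (amino
#'   acids), `I` (identity fraction), `score` (sum of contributing hit
#'   scores), `n_hits`.
#' @export
merge_hits <- function(hits) {
  hits <- data.table::as.data.table(hits)
  assert_that(nrow(hits) > 0, "merge_hits: empty hit list")
  assert_that(length(unique(hits$query_id)) == 1L &&
                length(unique(hits$subject_id)) == 1L,
              "merge_hits: hits must share one query-subject pair")
  o <- order(-hits$score, hits$qstart, hits$qend)
  covered <- integer(0)
  match_nt <- 0
  score <- 0
  for (i in o) {
    pos <- hits$qstart[i]:hits$qend[i]
    new <- setdiff(pos, covered)
    if (!length(new)) next
    density <- min(1, 3 * hits$matches[i] / length(pos))
    match_nt <- match_nt + density * length(new)
    covered <- c(covered, new)
    score <- score + hits$score[i]
  }
  L <- as.integer(round(length(covered) / 3))
  data.table::data.table(query_id = hits$query_id[1],
                         subject_id = hits$subject_id[1],
                         L = L, I = min(1, match_nt / length(covered)),
                         score = score, n_hits = nrow(hits))
}

# Merge all hits of one query, per subject.
merge_hits_by_subject <- function(hits) {
  if (nrow(hits) == 0L)
    return(data.table::data.table(query_id = character(),
                                  subject_id = character(), L = integer(),
                                  I = numeric(), score = numeric(),
                                  n_hits = integer()))
  parts <- split(hits, hits$subject_id)
  data.table::rbindlist(lapply(parts, merge_hits))
}
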