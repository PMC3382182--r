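# Minimal MEGAN-style lowest-common-ancestor assignment with min-score,
# top-percent, and min-support rules.

#' Define a taxonomy tree
#' @param edges `data.frame(taxon, parent)`; the root's parent is `NA`.
#' @return a `Taxonomy` list with `edges` and a path lookup.
#' @export
taxonomy_tree <- function(edges) {
  edges <- data.table::as.data.table(edges)
  assert_that(sum(is.na(edges$parent)) == 1L,
              "taxonomy needs exactly one root")
  paths <- list()
  for (tx in edges$taxon) {
    path <- tx
    cur <- tx
    repeat {
      p <- edges$parent[edges$taxon == cur]
      if (length(p) == 0L) stopf("unknown taxon label '%s'", cur)
      if (is.na(p)) break
      path <- c(p, path)
      cur <- p
    }
    paths[[tx]] <- path
  }
  structure(list(edges = edges, paths = paths), class = "Taxonomy")
}

lca_of <- function(tree, taxa) {
  taxa <- unique(taxa)
  unknown <- setdiff(taxa, names(tree$paths))
  assert_that(length(unknown) == 0, "unknown taxon label '%s'", unknown[1])
  paths <- tree$paths[taxa]
  depth <- min(lengths(paths))
  lca <- paths[[1]][1]
  for (d in seq_len(depth)) {
    level <- vapply(paths, `[[`, "", d)
    if (length(unique(level)) > 1L) break
    lca <- level[1]
  }
  lca
}

#' MEGAN-style LCA assignment of queries from scored hits
#'
#' Per query, hits with score below `min_score` or below
#' `(1 - top_percent/100)` of the query's best score are dropped; the query
#' is assigned to the lowest common ancestor of the remaining hit taxa.
#' After the batch pass, every taxon supported by fewer than `min_support`
#' queries has its queries raised to the parent taxon, repeatedly, until
#' all assigned taxa meet the support rule (the root is never raised).
#'
#' @param hits `data.table` with `query_id`, `taxon`, `score`.
#' @param tree a [taxonomy_tree()].
#' @param min_score minimum hit score.
#' @param top_percent retain hits within this percentage of the best score.
#' @param min_support minimum queries per assigned taxon.
#' @return `data.table`: `query_id`, `taxon` (`NA` = unassigned).
#' @export
lca_assign <- function(hits, tree, min_score = 35, top_percent = 10,
                       min_support = 5) {
  hits <- data.table::as.data.table(hits)
  unknown <- setdiff(unique(hits$taxon), names(tree$paths))
  assert_that(length(unknown) == 0, "unknown taxon label '%s'", unknown[1])
  qids <- unique(hits$query_id)
  asn <- vapply(qids, function(q) {
    h <- hits[hits$query_id == q & hits$score >= min_score]
    if (nrow(h) == 0L) return(NA_character_)
    h <- h[h$score >= (1 - top_percent / 100) * max(h$score)]
    lca_of(tree, h$taxon)
  }, "")
  out <- data.table::data.table(query_id = qids, taxon = asn)
  root <- tree$edges$taxon[is.na(tree$edges$parent)]
  repeat {
    counts <- table(out$taxon[!is.na(out$taxon)])
    low <- names(counts)[counts < min_support]
    low <- setdiff(low, root)
    if (!length(low)) break
    # raise the deepest under-supported taxon first
    depths <- lengths(tree$paths[low])
    tx <- low[which.max(depths)]
    parent <- tree$edges$parent[tree$edges$taxon == tx]
    out$taxon[!is.na(out$taxon) & out$taxon == tx] <- parent
  }
  out
}
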