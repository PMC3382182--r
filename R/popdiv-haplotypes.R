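# Minimum-haplotype decomposition: reads sharing recurrent, co-occurring
# changes at filtered variant positions define a genotype; singleton-style
# groups are folded into their nearest haplotype.

# Per-read variant signature restricted to the filtered variant positions.
read_signatures <- function(alignments, ref, region, var_pos) {
  refb <- seq_chars(ref$chromosomes[[region$chrom]])
  lapply(seq_len(nrow(alignments)), function(i) {
    pr <- cigar_pairs(alignments$cigar[i], alignments$start[i])
    on_var <- pr$ref %in% var_pos
    cov <- pr$ref[on_var]
    bases <- seq_chars(alignments$seq[i])[pr$qry[on_var] + 1L]
    diff <- bases != refb[cov + 1L]
    list(covered = cov, sig_pos = cov[diff], sig_allele = bases[diff])
  })
}

sig_key <- function(s) {
  if (!length(s$sig_pos)) return("")
  paste(sprintf("%d:%s", s$sig_pos, s$sig_allele), collapse = ",")
}

sig_distance <- function(a, b) {
  sa <- strsplit(a, ",", fixed = TRUE)[[1]]
  sb <- strsplit(b, ",", fixed = TRUE)[[1]]
  length(setdiff(sa, sb)) + length(setdiff(sb, sa))
}

#' Minimum-haplotype decomposition of a mapped region
#'
#' Variant positions are those passing [call_variants()] on the region
#' pileup. Reads covering at least `min_shared_positions` variant positions
#' are informative; they are grouped by their exact (position, allele)
#' signature. A non-reference haplotype is declared when at least
#' `min_reads` reads share at least `min_shared_positions` identical
#' changes; reads matching the reference at all covered variant positions
#' form the reference haplotype. Undeclared groups are folded into the
#' nearest declared haplotype (symmetric-difference distance on
#' signatures; ties favour the reference).
#'
#' @param alignments alignments of the reads in the region.
#' @param ref a `ReferenceGenome`.
#' @param region list `(chrom, start, end)`, 0-based half-open.
#' @param min_shared_positions minimum co-occurring changes per haplotype.
#' @param min_reads minimum supporting reads per haplotype.
#' @param min_cov,min_alt_reads,min_freq variant-filter settings passed to
#'   [call_variants()] for discovering candidate positions. The frequency
#'   floor defaults to 0.05 here (not the 0.15 used for reporting
#'   single-nucleotide variability): the decomposition's own recurrence
#'   rule provides specificity, and a 15% floor would censor genuine minor
#'   genotypes segregating near 15% abundance.
#' @return a `HaplotypeSet`: list with `haplotypes` (`data.table`:
#'   `signature`, `n_reads`, `frequency`, `is_reference`), `n_min`,
#'   `n_informative`, `variant_positions`.
#' @export
min_haplotypes <- function(alignments, ref, region,
                           min_shared_positions = 2L, min_reads = 2L,
                           min_cov = 5L, min_alt_reads = 2L,
                           min_freq = 0.05) {
  region <- as.list(region)
  names(region)[1:3] <- c("chrom", "start", "end")
  alignments <- alignments[alignments$chrom == region$chrom &
                             alignments$start < region$end &
                             alignments$end > region$start]
  assert_that(nrow(alignments) > 0, "no reads cover the region")
  cols <- pileup(alignments, ref, region)
  vars <- call_variants(cols, min_cov, min_alt_reads, min_freq)
  var_pos <- unique(vars$pos)

  if (!length(var_pos)) {
    hap <- data.table::data.table(signature = "", n_reads = nrow(alignments),
                                  frequency = 1, is_reference = TRUE)
    return(structure(list(haplotypes = hap, n_min = 1L,
                          n_informative = nrow(alignments),
                          variant_positions = integer(0)),
                     class = "HaplotypeSet"))
  }

  sigs <- read_signatures(alignments, ref, region, var_pos)
  # a region with fewer variant positions than min_shared_positions can
  # still be decomposed: informativeness adapts to what is observable
  need_cover <- min(min_shared_positions, length(var_pos))
  informative <- vapply(sigs, function(s)
    length(s$covered) >= need_cover, TRUE)
  assert_that(any(informative), "no informative reads in the region")
  sigs <- sigs[informative]
  keys <- vapply(sigs, sig_key, "")
  tab <- table(keys)
  grp <- data.table::data.table(signature = names(tab),
                                n_reads = as.integer(tab))
  grp$n_changes <- vapply(grp$signature, function(s)
    if (s == "") 0L else length(strsplit(s, ",", fixed = TRUE)[[1]]), 0L)

  # declaration pass, most complete signatures first: a group whose
  # signature is a subset of an already-declared haplotype does not found a
  # new one (minimum-genotype principle: reads that simply fail to cover
  # every variant position are explained by the existing haplotype)
  data.table::setorderv(grp, c("n_changes", "n_reads"), c(-1L, -1L))
  declared <- character(0)
  for (i in seq_len(nrow(grp))) {
    if (grp$signature[i] == "") next
    if (grp$n_changes[i] < min_shared_positions ||
        grp$n_reads[i] < min_reads) next
    sig_set <- strsplit(grp$signature[i], ",", fixed = TRUE)[[1]]
    subsumed <- any(vapply(declared, function(d)
      all(sig_set %in% strsplit(d, ",", fixed = TRUE)[[1]]), TRUE))
    if (!subsumed) declared <- c(declared, grp$signature[i])
  }
  has_ref_reads <- "" %in% grp$signature
  hap_sigs <- c(if (has_ref_reads || length(declared) == 0L) "", declared)

  # assignment pass: a read joins the haplotype it is consistent with
  # (matching alleles at every covered variant position); inconsistent
  # reads fold into the nearest haplotype, ties favouring the reference
  hap_changes <- lapply(hap_sigs, function(s)
    if (s == "") character(0) else strsplit(s, ",", fixed = TRUE)[[1]])
  counts <- integer(length(hap_sigs))
  for (s in sigs) {
    read_changes <- if (length(s$sig_pos))
      sprintf("%d:%s", s$sig_pos, s$sig_allele) else character(0)
    consistent <- vapply(hap_changes, function(h) {
      h_here <- h[as.integer(sub(":.*", "", h)) %in% s$covered]
      setequal(h_here, read_changes)
    }, TRUE)
    target <- if (any(consistent)) which(consistent)[1]
    else {
      key <- paste(read_changes, collapse = ",")
      d <- vapply(hap_sigs, sig_distance, 0, a = key)
      cand <- which(d == min(d))
      if (1L %in% cand && hap_sigs[1] == "") 1L else cand[1]
    }
    counts[target] <- counts[target] + 1L
  }
  n_inf <- length(sigs)
  out <- data.table::data.table(signature = hap_sigs, n_reads = counts,
                                frequency = counts / n_inf,
                                is_reference = hap_sigs == "")
  out <- out[out$n_reads > 0L]
  data.table::setorderv(out, "n_reads", -1L)
  structure(list(haplotypes = out, n_min = nrow(out), n_informative = n_inf,
                 variant_positions = sort(var_pos)),
            class = "HaplotypeSet")
}

#' @export
print.HaplotypeSet <- function(x, ...) {
  cat(sprintf("HaplotypeSet: n_min = %d over %d informative reads (%s)\n",
              x$n_min, x$n_informative,
              paste(sprintf("%.0f%%", 100 * x$haplotypes$frequency),
                    collapse = "/")))
  invisible(x)
}
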