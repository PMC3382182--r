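#' Describe one genotype of a mixed population
#'
#' @param label genotype name.
#' @param abundance relative abundance in (0,1]; abundances across a
#'   community must sum to 1.
#' @param snp_rate substitution rate per base relative to the reference,
#'   in `[0, 0.2]`.
#' @param intron_edits list of edits, each
#'   `list(feature = <rRNA feature id>, present = TRUE/FALSE, length = <bp>)`.
#'   `present = TRUE` inserts an intron of the given length into the feature;
#'   `FALSE` leaves the reference (intron-free) allele.
#' @param snps optional `data.frame(chrom, pos, alt)` of explicit
#'   substitutions (0-based positions) planted in addition to the random
#'   ones.
#' @return a `GenotypeSpec` (list).
#' @export
genotype_spec <- function(label, abundance, snp_rate = 0,
                          intron_edits = list(), snps = NULL) {
  assert_that(abundance > 0 && abundance <= 1,
              "abundance of '%s' must be in (0,1]", label)
  assert_that(snp_rate >= 0 && snp_rate <= 0.2,
              "snp_rate of '%s' must be in [0, 0.2]", label)
  structure(list(label = label, abundance = abundance, snp_rate = snp_rate,
                 intron_edits = intron_edits,
                 snps = if (!is.null(snps)) data.table::as.data.table(snps)),
            class = "GenotypeSpec")
}

# Deterministic intron sequence for a feature: depends only on the feature id
# and length, so all genotypes carrying the edit share the same intron.
intron_sequence <- function(feature_id, length, gc = 0.42) {
  with_seed(sum(utf8ToInt(feature_id)) * 1000L + length,
            random_dna(length, gc))
}

# Insertion point of an intron within a feature, in reference coordinates
# (0-based, the base before which the intron is inserted). LSU introns sit
# near the end of the gene; others are internal.
intron_insert_at <- function(feature) {
  if (feature$type == "rRNA-LSU") feature$end - 30L
  else feature$start + as.integer(0.7 * (feature$end - feature$start))
}

#' Plant genotypes (SNPs and rRNA intron alleles) on a reference
#'
#' Each genotype genome is the reference with independent random
#' substitutions at `snp_rate` plus any intron insertions. Substitution
#' positions and alleles are recorded in reference coordinates as ground
#' truth.
#'
#' @param ref a [reference_genome()].
#' @param specs list of [genotype_spec()] objects; abundances must sum to 1.
#' @param seed integer seed.
#' @return a `GenotypeSet`: list with `genotypes` (each carrying `label`,
#'   `abundance`, `chromosomes`, `variants`, `introns`) and `ref`.
#' @export
plant_genotypes <- function(ref, specs, seed = 1L) {
  ab <- vapply(specs, `[[`, 0, "abundance")
  assert_that(abs(sum(ab) - 1) <= 1e-9, "abundances must sum to 1 (got %g)",
              sum(ab))
  feats <- ref$features
  genotypes <- with_seed(seed, lapply(specs, function(sp) {
    chroms <- ref$chromosomes
    variants <- list()
    for (cid in names(chroms)) {
      if (sp$snp_rate > 0) {
        mut <- mutate_bases(seq_chars(chroms[[cid]]), sp$snp_rate)
        if (length(mut$positions)) {
          variants[[cid]] <- data.table::data.table(
            chrom = cid, pos = mut$positions - 1L,
            ref = seq_chars(ref$chromosomes[[cid]])[mut$positions],
            alt = mut$bases[mut$positions])
          chroms[[cid]] <- paste(mut$bases, collapse = "")
        }
      }
    }
    if (!is.null(sp$snps) && nrow(sp$snps)) {
      for (i in seq_len(nrow(sp$snps))) {
        cid <- sp$snps$chrom[i]
        p1 <- sp$snps$pos[i] + 1L
        refb <- substr(ref$chromosomes[[cid]], p1, p1)
        substr(chroms[[cid]], p1, p1) <- sp$snps$alt[i]
        variants[[paste0("x", cid, i)]] <- data.table::data.table(
          chrom = cid, pos = sp$snps$pos[i], ref = refb,
          alt = sp$snps$alt[i])
      }
    }
    introns <- list()
    for (ed in sp$intron_edits) {
      frow <- feats[id == ed$feature]
      if (nrow(frow) == 0)
        stopf("intron edit refers to missing feature '%s'", ed$feature)
      frow <- as.list(frow[1])
      at <- intron_insert_at(frow)
      iseq <- intron_sequence(ed$feature, ed$length)
      if (isTRUE(ed$present)) {
        s <- chroms[[frow$chrom]]
        chroms[[frow$chrom]] <- paste0(substr(s, 1, at),
                                       iseq,
                                       substr(s, at + 1L, nchar(s)))
      }
      introns[[length(introns) + 1L]] <- data.table::data.table(
        feature = ed$feature, chrom = frow$chrom, present = isTRUE(ed$present),
        length = ed$length, insert_at = at)
    }
    list(label = sp$label, abundance = sp$abundance, chromosomes = chroms,
         variants = if (length(variants))
           data.table::rbindlist(variants) else
             data.table::data.table(chrom = character(), pos = integer(),
                                    ref = character(), alt = character()),
         introns = if (length(introns)) data.table::rbindlist(introns) else
           data.table::data.table(feature = character(), chrom = character(),
                                  present = logical(), length = integer(),
                                  insert_at = integer()))
  }))
  structure(list(genotypes = genotypes, ref = ref), class = "GenotypeSet")
}

#' @export
print.GenotypeSet <- function(x, ...) {
  cat(sprintf("GenotypeSet: %d genotypes (%s)\n", length(x$genotypes),
              paste(sprintf("%s@%.2f", vapply(x$genotypes, `[[`, "", "label"),
                            vapply(x$genotypes, `[[`, 0, "abundance")),
                    collapse = ", ")))
  invisible(x)
}
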