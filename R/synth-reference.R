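#' Reference genome container
#'
#' Bundles chromosome sequences with per-chromosome categories and feature
#' annotation. Coordinates are 0-based half-open internally; exporters emit
#' 1-based closed coordinates.
#'
#' @param chromosomes named character vector of DNA sequences.
#' @param category named character vector, one of `"nuclear-standard"`,
#'   `"nuclear-outlier"`, `"organelle"`, aligned with `chromosomes`.
#' @param features `data.table` with columns `id`, `chrom`, `start`, `end`
#'   (0-based half-open), `type` (`CDS`, `rRNA-SSU`, `rRNA-LSU`, `ITS`),
#'   `strand`.
#' @return an object of class `ReferenceGenome`.
#' @export
reference_genome <- function(chromosomes, category, features) {
  assert_that(length(chromosomes) > 0 && sum(nchar(chromosomes)) > 0,
              "reference genome must have positive total length")
  assert_that(!anyDuplicated(names(chromosomes)),
              "chromosome ids must be unique")
  assert_that(all(names(chromosomes) %in% names(category)),
              "every chromosome needs a category")
  features <- data.table::as.data.table(features)
  lens <- nchar(chromosomes)
  if (nrow(features)) {
    bad <- features[!(chrom %in% names(chromosomes)) | start < 0 |
                      end > lens[chrom] | start >= end]
    assert_that(nrow(bad) == 0, "feature(s) outside chromosome bounds: %s",
                paste(utils::head(bad$id, 3), collapse = ", "))
  }
  structure(list(chromosomes = chromosomes,
                 category = category[names(chromosomes)],
                 features = features),
            class = "ReferenceGenome")
}

#' @export
print.ReferenceGenome <- function(x, ...) {
  cat(sprintf("ReferenceGenome: %d chromosomes, %s bp total, %d features\n",
              length(x$chromosomes),
              format(sum(nchar(x$chromosomes)), big.mark = ","),
              nrow(x$features)))
  invisible(x)
}

#' Chromosome lengths of a reference genome
#' @param ref a `ReferenceGenome`.
#' @return named integer vector.
#' @export
chrom_lengths <- function(ref) {
  stats::setNames(nchar(ref$chromosomes), names(ref$chromosomes))
}

#' Describe one chromosome for the genome simulator
#'
#' @param id chromosome id.
#' @param length total length in bp (single-segment shorthand), or `NULL`
#'   when `segments` is given.
#' @param gc target GC fraction (single-segment shorthand).
#' @param category chromosome category.
#' @param segments optional `data.frame(length, gc)` for chromosomes with a
#'   segmented base composition (e.g. the tri-partite low-GC outlier).
#' @return a chromosome plan entry (list).
#' @export
chromosome_plan <- function(id, length = NULL, gc = NULL,
                            category = "nuclear-standard", segments = NULL) {
  if (is.null(segments)) {
    segments <- data.frame(length = length, gc = gc)
  }
  list(id = id, category = category, segments = segments)
}

#' Default scaled-down genome plan
#'
#' Emulates the stated world at desk scale: a ~1 Mbp genome with
#' GC-homogeneous standard nuclear chromosomes around 48% GC, one large
#' tri-partite outlier chromosome (47/39/47% GC), one small low-GC outlier,
#' and two low-GC organelles.
#'
#' @return list of chromosome plan entries.
#' @export
default_reference_plan <- function() {
  std_gc <- c(0.489, 0.486, 0.486, 0.483, 0.483, 0.486, 0.483, 0.485, 0.481,
              0.470)
  std_len <- c(150000, 130000, 120000, 110000, 100000, 90000, 80000, 70000,
               60000, 50000)
  plan <- Map(function(i, l, g)
    chromosome_plan(sprintf("chr_%02d", i), l, g), seq_along(std_len),
    std_len, std_gc)
  plan <- c(plan, list(
    chromosome_plan("chr_outlier", category = "nuclear-outlier",
                    segments = data.frame(length = c(30000, 40000, 30000),
                                          gc = c(0.47, 0.39, 0.47))),
    chromosome_plan("chr_small_outlier", 25000, 0.42, "nuclear-outlier"),
    chromosome_plan("chloroplast", 20000, 0.41, "organelle"),
    chromosome_plan("mitochondrion", 15000, 0.40, "organelle")))
  plan
}

# Place non-overlapping CDS features along a chromosome, skipping a masked
# interval (the rRNA operon). Lengths are multiples of 3.
place_cds <- function(chrom_id, chrom_len, mask = NULL) {
  pos <- 0L
  rows <- list()
  n <- 0L
  while (pos < chrom_len - 2000L) {
    gap <- sample(200:800, 1L)
    len <- 3L * sample(200:600, 1L)
    start <- pos + gap
    end <- start + len
    if (end > chrom_len) break
    if (!is.null(mask) && start < mask[2] && end > mask[1]) {
      pos <- mask[2]
      next
    }
    n <- n + 1L
    rows[[n]] <- data.table::data.table(
      id = sprintf("cds_%s_%04d", chrom_id, n), chrom = chrom_id,
      start = start, end = end, type = "CDS",
      strand = sample(c("+", "-"), 1L))
    pos <- end
  }
  data.table::rbindlist(rows)
}

#' Simulate a multi-chromosome reference genome
#'
#' Generates chromosome sequences segment by segment at the planned GC
#' targets, annotates CDS features on nuclear chromosomes, and places a
#' single rRNA operon (SSU-ITS-LSU, 5646 bp) on a designated chromosome.
#'
#' @param plan list of [chromosome_plan()] entries
#'   (default [default_reference_plan()]).
#' @param seed integer seed; identical `(plan, seed)` give byte-identical
#'   genomes.
#' @param rrna_chrom id of the chromosome carrying the rRNA operon; default
#'   is the first nuclear chromosome; `NA` skips the operon.
#' @param annotate_cds logical; place CDS features on nuclear chromosomes.
#' @return a [reference_genome()] object.
#' @export
simulate_reference <- function(plan = default_reference_plan(), seed = 1L,
                               rrna_chrom = NULL, annotate_cds = TRUE) {
  for (p in plan) {
    if (sum(p$segments$length) < 1000)
      stopf("chromosome '%s': planned length below 1 kbp", p$id)
    if (any(p$segments$gc <= 0 | p$segments$gc >= 1))
      stopf("chromosome '%s': GC target outside (0,1)", p$id)
  }
  ids <- vapply(plan, `[[`, "", "id")
  assert_that(!anyDuplicated(ids), "duplicate chromosome ids in plan")
  with_seed(seed, {
    seqs <- vapply(plan, function(p) {
      paste(mapply(random_dna, p$segments$length, p$segments$gc),
            collapse = "")
    }, "")
    names(seqs) <- ids
    category <- stats::setNames(vapply(plan, `[[`, "", "category"), ids)
    nuclear <- ids[category != "organelle"]
    if (is.null(rrna_chrom)) rrna_chrom <- nuclear[1]

    rrna <- NULL
    op_start <- NA_integer_
    op_total <- 0L
    if (!is.na(rrna_chrom)) {
      assert_that(rrna_chrom %in% ids, "rrna_chrom '%s' not in plan",
                  rrna_chrom)
      # rRNA operon: SSU 1800, ITS 546, LSU 3300 (5646 bp total)
      op_len <- c(SSU = 1800L, ITS = 546L, LSU = 3300L)
      op_total <- sum(op_len)
      clen <- nchar(seqs[rrna_chrom])
      assert_that(clen >= op_total + 2000L,
                  "chromosome '%s' too short for the rRNA operon", rrna_chrom)
      op_start <- sample(1000:(clen - op_total - 1000L), 1L)
      starts <- op_start + c(0L, cumsum(op_len))[1:3]
      rrna <- data.table::data.table(
        id = c("rRNA_SSU", "ITS", "rRNA_LSU"), chrom = rrna_chrom,
        start = starts, end = starts + op_len,
        type = c("rRNA-SSU", "ITS", "rRNA-LSU"), strand = "+")
    }

    feats <- rrna
    if (annotate_cds) {
      cds <- data.table::rbindlist(lapply(nuclear, function(id) {
        mask <- if (!is.na(rrna_chrom) && id == rrna_chrom)
          c(op_start, op_start + op_total) else NULL
        place_cds(id, nchar(seqs[id]), mask)
      }))
      feats <- data.table::rbindlist(c(list(cds), list(rrna)))
    }
    if (is.null(feats))
      feats <- data.table::data.table(id = character(), chrom = character(),
                                      start = integer(), end = integer(),
                                      type = character(), strand = character())
    reference_genome(seqs, category, feats)
  })
}
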