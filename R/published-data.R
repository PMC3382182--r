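# Bundled reference dataset: published per-chromosome mapping statistics of
# two flow-sorted Pacific picoplankton samples (T142, T149) assembled
# against the Bathycoccus prasinos RCC1105 genome, plus the corresponding
# read statistics and three-chromosome identity table. These are printed
# summary values, used as desk-check inputs for the analytics functions.

published_path <- function(file) {
  p <- system.file("extdata", file, package = "picometa")
  assert_that(nzchar(p), "bundled table '%s' not found", file)
  p
}

#' Published per-chromosome mapping statistics (samples T142/T149)
#'
#' 21 nuclear chromosomes plus chloroplast and mitochondrion of the
#' *Bathycoccus prasinos* RCC1105 genome: length, GC%, and per-sample read
#' counts, covered bp, coverage %, coverage depth and identical-sites %.
#'
#' @return `data.table`, one row per chromosome.
#' @export
published_mapping_stats <- function() {
  data.table::fread(published_path("bathycoccus_mapping_by_chromosome.tsv"))
}

#' Published read statistics for samples T142/T149
#' @return `data.table`, one row per sample.
#' @export
published_read_stats <- function() {
  data.table::fread(published_path("bathycoccus_read_stats.tsv"))
}

#' Published three-chromosome masked identity table
#'
#' Per-chromosome alignment lengths and percent identical sites (three-way
#' and pairwise, CDS/non-CDS split) for the three largest chromosomes,
#' restricted to regions covered at >= 10x in both samples.
#'
#' @return `data.table`, one row per chromosome.
#' @export
published_identity_table <- function() {
  data.table::fread(published_path("bathycoccus_three_chrom_identity.tsv"))
}
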