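# Shared fixtures, memoised so expensive objects are built once per run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# Small 4-chromosome genome (~90 kbp) for mapping/coverage tests.
tiny_plan <- function() {
  list(chromosome_plan("tc1", 40000, 0.48),
       chromosome_plan("tc2", 25000, 0.47),
       chromosome_plan("tc3", 15000, 0.42, "nuclear-outlier"),
       chromosome_plan("torg", 10000, 0.40, "organelle"))
}

tiny_ref <- function() memo("tiny_ref", {
  simulate_reference(tiny_plan(), seed = 42, rrna_chrom = NA,
                     annotate_cds = FALSE)
})

# 2 genera x 2 species taxonomy plan used across classifier tests.
toy_taxa <- function() {
  data.frame(genome = c("Gen1_sp1", "Gen1_sp2", "Gen2_sp1", "Gen2_sp2"),
             genus = c("Genus1", "Genus1", "Genus2", "Genus2"),
             class = "ClassA")
}

toy_db <- function() memo("toy_db", {
  simulate_protein_families(40, toy_taxa(), seed = 11)
})

toy_matrix <- function() memo("toy_matrix", build_threshold_matrix(toy_db()))

# Build an alignment table row for an ungapped read placed at `start`
# (0-based) on `chrom`; convenience for constructing exact pileups.
ungapped_row <- function(read_id, chrom, start, seq, strand = "+") {
  data.table::data.table(read_id = read_id, chrom = chrom,
                         start = as.integer(start),
                         end = as.integer(start + nchar(seq)),
                         strand = strand,
                         cigar = paste0(nchar(seq), "M"), seq = seq,
                         mismatches = NA_integer_, alen = nchar(seq),
                         identity = NA_real_, score = NA_real_)
}

random_reads_dt <- function(n, len = 60, seed = 1) {
  withr::with_seed(seed, {
    data.table::data.table(
      id = sprintf("r%03d", seq_len(n)),
      seq = vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
              collapse = ""), ""),
      qual = strrep("?", len))
  })
}
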