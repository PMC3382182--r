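# Synthetic data generators: reference genomes, genotype planting,
# MDA-biased reads, protein families.

test_that("simulate_reference honours GC targets, determinism and errors", {
  plan <- list(
    chromosome_plan("flat", 100000, 0.50),
    chromosome_plan("tri", category = "nuclear-outlier",
                    segments = data.frame(length = c(50000, 60000, 50000),
                                          gc = c(0.47, 0.39, 0.47))))
  ref <- simulate_reference(plan, seed = 5, rrna_chrom = "flat")
  expect_s3_class(ref, "ReferenceGenome")

  # law of large numbers at the stated tolerance
  expect_gt(gc_content(ref$chromosomes[["flat"]]), 0.485)
  expect_lt(gc_content(ref$chromosomes[["flat"]]), 0.515)

  # tri-partite outlier: per-segment GC within 1.5 points of target
  tri <- ref$chromosomes[["tri"]]
  segs <- c(gc_content(substr(tri, 1, 50000)),
            gc_content(substr(tri, 50001, 110000)),
            gc_content(substr(tri, 110001, 160000)))
  expect_equal(segs, c(0.47, 0.39, 0.47), tolerance = 0.015 / 0.4)
  expect_true(all(abs(segs - c(0.47, 0.39, 0.47)) < 0.015))

  # seeded determinism: byte-identical output
  ref2 <- simulate_reference(plan, seed = 5, rrna_chrom = "flat")
  expect_identical(ref$chromosomes, ref2$chromosomes)
  expect_identical(ref$features, ref2$features)

  # rRNA operon placed on the designated chromosome
  expect_setequal(
    ref$features[ref$features$type %in% c("rRNA-SSU", "ITS", "rRNA-LSU")]$chrom,
    "flat")

  # invalid plans are rejected with the chromosome named
  expect_error(simulate_reference(list(chromosome_plan("bad", 500, 0.5))),
               "bad")
  expect_error(simulate_reference(list(chromosome_plan("badgc", 5000, 1.2))),
               "badgc")
})

test_that("plant_genotypes: identity case, intron length, SNP truth", {
  ref <- tiny_ref()
  # a clean genotype is byte-identical with an empty truth list
  gs <- plant_genotypes(ref, list(genotype_spec("clean", 1)), seed = 1)
  expect_identical(gs$genotypes[[1]]$chromosomes, ref$chromosomes)
  expect_equal(nrow(gs$genotypes[[1]]$variants), 0)

  # snp_rate on a known length: observed fraction within 3 sigma binomial
  plan <- list(chromosome_plan("big", 200000, 0.48))
  bigref <- simulate_reference(plan, seed = 2, rrna_chrom = NA,
                               annotate_cds = FALSE)
  rate <- 0.03
  gs2 <- plant_genotypes(bigref, list(genotype_spec("mut", 1,
                                                    snp_rate = rate)),
                         seed = 3)
  n <- nrow(gs2$genotypes[[1]]$variants)
  sigma <- sqrt(rate * (1 - rate) * 200000)
  expect_lt(abs(n - rate * 200000), 3 * sigma)
  # every truth row records a real substitution
  v <- gs2$genotypes[[1]]$variants
  i <- sample(nrow(v), 25)
  expect_true(all(substring(gs2$genotypes[[1]]$chromosomes[["big"]],
                            v$pos[i] + 1, v$pos[i] + 1) == v$alt[i]))
  expect_true(all(substring(bigref$chromosomes[["big"]],
                            v$pos[i] + 1, v$pos[i] + 1) == v$ref[i]))

  # intron edit changes length by exactly the intron length
  opref <- simulate_reference(seed = 7)
  gs3 <- plant_genotypes(opref, list(
    genotype_spec("int", 1, intron_edits = list(
      list(feature = "rRNA_SSU", present = TRUE, length = 433)))), seed = 4)
  rchrom <- opref$features[opref$features$id == "rRNA_SSU"]$chrom
  expect_equal(nchar(gs3$genotypes[[1]]$chromosomes[[rchrom]]),
               nchar(opref$chromosomes[[rchrom]]) + 433)

  # edit on a missing feature names the feature
  expect_error(plant_genotypes(opref, list(
    genotype_spec("x", 1, intron_edits = list(
      list(feature = "nope", present = TRUE, length = 10)))), seed = 1),
    "nope")
  # abundances must sum to one
  expect_error(plant_genotypes(ref, list(genotype_spec("a", 0.5)), seed = 1),
               "sum to 1")
})

test_that("simulate_mda_reads: contracts, determinism, abundance recovery", {
  ref <- tiny_ref()
  gs <- plant_genotypes(ref, list(genotype_spec("A", 0.7),
                                  genotype_spec("B", 0.3, snp_rate = 0.01)),
                        seed = 1)
  empty <- simulate_mda_reads(gs, 0, mda_params(), seed = 1)
  expect_equal(nrow(empty$reads), 0)
  expect_equal(nrow(empty$truth), 0)
  expect_error(simulate_mda_reads(gs, -1, mda_params(), seed = 1), "n_reads")

  law <- c(min = 40, max = 800, mean = 300, shape = 0.4)
  rs <- simulate_mda_reads(gs, 2000, mda_params(read_length_law = law),
                           seed = 6)
  expect_equal(nrow(rs$reads), 2000)
  # one truth row per read
  expect_setequal(rs$reads$id, rs$truth$read_id)
  lens <- nchar(rs$reads$seq)
  expect_true(all(lens >= 40 & lens <= 800))
  # determinism
  rs2 <- simulate_mda_reads(gs, 2000, mda_params(read_length_law = law),
                            seed = 6)
  expect_identical(rs$reads, rs2$reads)

  # conservation: per-genome read share ~ abundance (3 sigma binomial)
  share <- mean(rs$truth$genome == "A")
  expect_lt(abs(share - 0.7), 3 * sqrt(0.7 * 0.3 / 2000))

  # truth intervals reproduce the read sequence (error-free, + strand)
  rs0 <- simulate_mda_reads(gs, 50, mda_params(error_rate = 0), seed = 2)
  tr <- rs0$truth[rs0$truth$strand == "+" & rs0$truth$genome == "A"]
  g <- gs$genotypes[[1]]$chromosomes
  i <- seq_len(min(10, nrow(tr)))
  expect_identical(
    rs0$reads$seq[match(tr$read_id[i], rs0$reads$id)],
    unname(substring(g[tr$chrom[i]], tr$start[i] + 1, tr$end[i])))
})

test_that("MDA bias: window-depth CV rises with log_sd; organelle boost", {
  plan <- list(chromosome_plan("u1", 60000, 0.48))
  ref <- simulate_reference(plan, seed = 3, rrna_chrom = NA,
                            annotate_cds = FALSE)
  gs <- plant_genotypes(ref, list(genotype_spec("g", 1)), seed = 1)
  law <- c(min = 100, max = 500, mean = 300, shape = 0.3)
  # 20x mean depth over 60 kbp at 300 bp reads -> 4000 reads
  window_cv <- function(log_sd, seed) {
    rs <- simulate_mda_reads(gs, 4000,
                             mda_params(log_sd = log_sd, gc_slope = 0,
                                        read_length_law = law,
                                        error_rate = 0), seed = seed)
    # oracle: direct per-window counts of covering reads
    depth <- integer(60000)
    for (i in seq_len(nrow(rs$truth)))
      depth[(rs$truth$start[i] + 1):rs$truth$end[i]] <-
        depth[(rs$truth$start[i] + 1):rs$truth$end[i]] + 1L
    wins <- split(depth, rep(1:6, each = 10000))
    mu <- vapply(wins, mean, 0)
    stats::sd(mu) / mean(mu)
  }
  for (s in 1:3) {
    cv0 <- window_cv(0, s)
    cv1 <- window_cv(1.2, s)
    expect_lt(cv0, 0.35)
    expect_gt(cv1, cv0)
  }
})

test_that("GC-coverage and organelle properties hold across seeds", {
  ref <- memo("gcprop_ref", simulate_reference(seed = 9))
  gs <- memo("gcprop_gs",
             plant_genotypes(ref, list(genotype_spec("g", 1)), seed = 1))
  nuclear <- names(ref$category)[ref$category != "organelle"]
  lens <- chrom_lengths(ref)
  rhos <- vapply(1:5, function(s) {
    rs <- simulate_mda_reads(gs, 4000, mda_params(error_rate = 0), seed = s)
    covfrac <- vapply(nuclear, function(cid) {
      tr <- rs$truth[rs$truth$chrom == cid]
      if (nrow(tr) == 0) return(0)
      covered_bp_oracle(tr$start, tr$end, lens[[cid]]) / lens[[cid]]
    }, 0)
    gcs <- gc_content(ref$chromosomes[nuclear])
    gc_coverage_correlation(gcs, covfrac)$rho
  }, 0)
  # sign test: positive rank correlation in the clear majority of seeds
  expect_gte(sum(rhos > 0), 4)

  # organelle copy number drives organelle depth above genome mean
  rs <- simulate_mda_reads(gs, 4000,
                           mda_params(organelle_copy_number = 20,
                                      error_rate = 0), seed = 17)
  mean_depth <- function(ids) {
    tr <- rs$truth[rs$truth$chrom %in% ids]
    sum(tr$end - tr$start) / sum(lens[ids])
  }
  org <- names(ref$category)[ref$category == "organelle"]
  expect_gt(mean_depth(org), mean_depth(names(lens)))
})

test_that("simulate_protein_families: structure, divergence, specificity", {
  db <- toy_db()
  expect_equal(nrow(db$taxonomy), 4)
  expect_error(simulate_protein_families(
    5, data.frame(genome = "g", genus = "x", class = "c")), "2 genera")

  pr <- db$proteins
  cnt <- table(pr$group)
  shared <- names(cnt)[cnt == 4]
  stopifnot(length(shared) >= 5)
  idents <- lapply(shared[1:8], function(g) {
    fam <- pr[pr$group == g]
    within_genus <- protein_pair_identity(
      fam$seq[fam$genome == "Gen1_sp1"], fam$seq[fam$genome == "Gen1_sp2"])
    cross_genus <- protein_pair_identity(
      fam$seq[fam$genome == "Gen1_sp1"], fam$seq[fam$genome == "Gen2_sp1"])
    c(within_genus$identity, cross_genus$identity)
  })
  m <- do.call(rbind, idents)
  expect_gt(mean(m[, 1]), mean(m[, 2]))

  # genome-specific families appear in exactly one genome
  solo <- names(cnt)[cnt == 1]
  expect_gt(length(solo), 0)

  # per-genome DNA carries each gene at its truth coordinates
  gd <- db$genomes_dna[["Gen1_sp1"]]
  gene <- gd$genes[1]
  dna <- substring(gd$seq, gene$start + 1, gene$end)
  if (gene$strand == "-")
    dna <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(dna)))
  expect_identical(aa, pr$seq[pr$id == gene$protein_id])
})
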