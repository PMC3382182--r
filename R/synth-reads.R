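#' MDA amplification-bias and read-length parameters
#'
#' The bias model multiplies three effects on the per-base read-start
#' weight: a smoothed per-anchor lognormal amplification field (long-range
#' coverage waves), a GC effect `exp(gc_slope * (local GC - genome GC))`
#' evaluated in 1 kbp windows, and a copy-number multiplier for organelle
#' chromosomes.
#'
#' @param anchor_spacing spacing of lognormal anchors in bp.
#' @param log_sd standard deviation of the per-anchor log-amplification
#'   factor; 0 disables MDA waviness (Poisson-like sampling).
#' @param gc_slope log-amplification per unit GC deviation; positive values
#'   under-amplify low-GC regions.
#' @param organelle_copy_number weight multiplier for organelle chromosomes.
#' @param read_length_law named vector `c(min, max, mean, shape)` of the
#'   truncated-lognormal read-length distribution (bp).
#' @param error_rate per-base substitution error rate of the sequencer.
#' @return an `MdaParams` list.
#' @export
mda_params <- function(anchor_spacing = 5000, log_sd = 1.2, gc_slope = 4,
                       organelle_copy_number = 20,
                       read_length_law = c(min = 40, max = 2044, mean = 420,
                                           shape = 0.5),
                       error_rate = 0.005) {
  assert_that(log_sd >= 0, "log_sd must be >= 0")
  rl <- read_length_law
  assert_that(rl[["min"]] <= rl[["mean"]] && rl[["mean"]] <= rl[["max"]],
              "read length law needs min <= mean <= max")
  structure(list(anchor_spacing = anchor_spacing, log_sd = log_sd,
                 gc_slope = gc_slope,
                 organelle_copy_number = organelle_copy_number,
                 read_length_law = rl, error_rate = error_rate),
            class = "MdaParams")
}

# Truncated lognormal read lengths: sdlog = shape, meanlog set so the
# untruncated mean equals `mean`; rejection into [min, max].
sample_read_lengths <- function(n, law) {
  if (n == 0L) return(integer(0))
  meanlog <- log(law[["mean"]]) - law[["shape"]]^2 / 2
  out <- integer(0)
  while (length(out) < n) {
    x <- stats::rlnorm(2L * (n - length(out)) + 10L, meanlog, law[["shape"]])
    x <- x[x >= law[["min"]] & x <= law[["max"]]]
    out <- c(out, as.integer(round(x)))
  }
  out[seq_len(n)]
}

# Per-base read-start weight for one chromosome of one genotype.
mda_weight_field <- function(seq, genome_gc, params) {
  L <- nchar(seq)
  field <- numeric(L)
  if (params$log_sd > 0) {
    anchors <- unique(c(seq(1L, L, by = params$anchor_spacing), L))
    vals <- stats::rnorm(length(anchors), 0, params$log_sd)
    field <- if (length(anchors) > 1L)
      stats::approx(anchors, vals, xout = seq_len(L), rule = 2)$y
    else rep(vals, L)
  }
  if (params$gc_slope != 0) {
    win <- 1000L
    nwin <- ceiling(L / win)
    starts <- (seq_len(nwin) - 1L) * win + 1L
    ends <- pmin(starts + win - 1L, L)
    wgc <- gc_content(substring(seq, starts, ends))
    field <- field + params$gc_slope *
      rep(wgc - genome_gc, times = ends - starts + 1L)
  }
  exp(field)
}

#' Simulate MDA-biased pyrosequencing reads from a genotype mixture
#'
#' Read start positions are drawn proportionally to genotype abundance
#' times the MDA weight field (see [mda_params()]); lengths follow the
#' truncated lognormal law; substitution errors are applied at
#' `params$error_rate`. Every read gets one ground-truth row.
#'
#' @param genomes a `GenotypeSet` from [plant_genotypes()].
#' @param n_reads number of reads (>= 0).
#' @param params an [mda_params()] object.
#' @param seed integer seed.
#' @return list with `reads` (`data.table`: `id`, `seq`, `qual`) and
#'   `truth` (`data.table`: `read_id`, `genome`, `chrom`, `start`, `end`
#'   0-based half-open in the genotype's coordinates, `strand`,
#'   `error_count`).
#' @export
simulate_mda_reads <- function(genomes, n_reads, params = mda_params(),
                               seed = 1L) {
  assert_that(n_reads >= 0, "n_reads must be >= 0")
  empty <- list(
    reads = data.table::data.table(id = character(), seq = character(),
                                   qual = character()),
    truth = data.table::data.table(read_id = character(), genome = character(),
                                   chrom = character(), start = integer(),
                                   end = integer(), strand = character(),
                                   error_count = integer()))
  if (n_reads == 0L) return(empty)
  category <- genomes$ref$category
  law <- params$read_length_law
  min_len <- as.integer(law[["min"]])

  with_seed(seed, {
    # per (genotype, chromosome) weight fields
    units <- list()
    for (g in genomes$genotypes) {
      ggc <- gc_content(paste(unlist(g$chromosomes), collapse = ""))
      for (cid in names(g$chromosomes)) {
        s <- g$chromosomes[[cid]]
        L <- nchar(s)
        if (L < min_len) next
        w <- g$abundance * mda_weight_field(s, ggc, params)
        if (identical(category[[cid]], "organelle"))
          w <- w * params$organelle_copy_number
        w[(L - min_len + 2L):L] <- 0  # starts that cannot fit a minimal read
        units[[length(units) + 1L]] <- list(genome = g$label, chrom = cid,
                                            seq = s, w = w, total = sum(w))
      }
    }
    # normalise weights within each genotype: the amplification field
    # redistributes coverage along a genome but read shares across
    # genotypes stay proportional to abundance (conservation invariant)
    genome_of <- vapply(units, `[[`, "", "genome")
    totals <- vapply(units, `[[`, 0, "total")
    ab <- vapply(genomes$genotypes, `[[`, 0, "abundance")
    names(ab) <- vapply(genomes$genotypes, `[[`, "", "label")
    per_genome_total <- tapply(totals, genome_of, sum)
    totals <- totals * ab[genome_of] / per_genome_total[genome_of]
    n_by_unit <- as.vector(stats::rmultinom(1L, n_reads, totals))

    reads <- vector("list", length(units))
    truth <- vector("list", length(units))
    offset <- 0L
    for (i in seq_along(units)) {
      n_i <- n_by_unit[i]
      if (n_i == 0L) next
      u <- units[[i]]
      L <- nchar(u$seq)
      starts <- sample.int(L, n_i, replace = TRUE, prob = u$w)
      lens <- sample_read_lengths(n_i, law)
      ends <- pmin(starts + lens - 1L, L)
      strands <- sample(c("+", "-"), n_i, replace = TRUE)
      seqs <- substring(u$seq, starts, ends)
      nerr <- integer(n_i)
      if (params$error_rate > 0) {
        for (j in seq_len(n_i)) {
          mut <- mutate_bases(seq_chars(seqs[j]), params$error_rate)
          nerr[j] <- length(mut$positions)
          if (nerr[j]) seqs[j] <- paste(mut$bases, collapse = "")
        }
      }
      neg <- strands == "-"
      if (any(neg)) seqs[neg] <- revcomp(seqs[neg])
      ids <- sprintf("read_%06d", offset + seq_len(n_i))
      offset <- offset + n_i
      reads[[i]] <- data.table::data.table(
        id = ids, seq = seqs,
        qual = strrep("?", nchar(seqs)))  # constant Q30
      truth[[i]] <- data.table::data.table(
        read_id = ids, genome = u$genome, chrom = u$chrom,
        start = starts - 1L, end = ends, strand = strands,
        error_count = nerr)
    }
    list(reads = data.table::rbindlist(reads),
         truth = data.table::rbindlist(truth))
  })
}
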