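AA_ALPHABET20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                   "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# aa -> synonymous codon table (stop codons excluded)
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  gc <- gc[gc != "*"]
  split(names(gc), gc)
}

mutate_protein <- function(aa, rate) {
  n <- length(aa)
  k <- stats::rbinom(1L, n, rate)
  if (k == 0L) return(aa)
  pos <- sample.int(n, k)
  for (i in pos) aa[i] <- sample(setdiff(AA_ALPHABET20, aa[i]), 1L)
  aa
}

# Back-translate an amino-acid vector with random synonymous codons.
back_translate <- function(aa, codons) {
  paste(vapply(aa, function(a) {
    cc <- codons[[a]]
    if (length(cc) == 1L) cc else sample(cc, 1L)
  }, ""), collapse = "")
}

#' Simulate ortholog protein families across a taxonomy plan
#'
#' Families evolve down a fixed class -> genus -> genome tree with
#' per-level substitution rates chosen so mean within-genus amino-acid
#' divergence approximates `divergence$genus` and within-class (across
#' genera) `divergence$class`. A fraction of families is genome-specific
#' (present in a single genome, no orthologs) to exercise the 80%/50-aa
#' default rule. Each genome also gets a nuclear DNA sequence built from
#' back-translated genes separated by random intergenic spacers, with gene
#' coordinates tracked as ground truth.
#'
#' @param n_families number of ortholog families.
#' @param taxa `data.frame(genome, genus, class)`; needs >= 2 genera.
#' @param divergence list with `genus` and `class` mean amino-acid
#'   divergences (class >= genus).
#' @param specific_frac fraction of genome-specific families.
#' @param loss_frac per-genome probability that a shared family's copy was
#'   lost (patchy presence/absence, the main source of wrong-genus best
#'   hits in leave-one-out validation).
#' @param length_range protein length range (amino acids).
#' @param seed integer seed.
#' @return a `ProteinDB`: list with `proteins` (`data.table`: `id`,
#'   `genome`, `genus`, `class`, `group`, `seq`), `taxonomy`, and
#'   `genomes_dna` (per genome: `seq` plus a `genes` table).
#' @export
simulate_protein_families <- function(n_families, taxa,
                                      divergence = list(genus = 0.10,
                                                        class = 0.40),
                                      specific_frac = 0.15,
                                      loss_frac = 0.15,
                                      length_range = c(150L, 400L),
                                      seed = 1L) {
  taxa <- data.table::as.data.table(taxa)
  assert_that(nrow(taxa) >= 2 && length(unique(taxa$genus)) >= 2,
              "taxa plan must contain at least 2 genera")
  assert_that(divergence$class >= divergence$genus,
              "class divergence must be >= genus divergence")
  d_g <- divergence$genus
  d_c <- divergence$class
  d_x <- min(0.6, 1.5 * d_c)
  codons <- codon_table()

  with_seed(seed, {
    prot <- vector("list", n_families * nrow(taxa))
    k <- 0L
    for (f in seq_len(n_families)) {
      len <- sample(length_range[1]:length_range[2], 1L)
      specific <- stats::runif(1) < specific_frac
      gid <- sprintf("fam_%04d", f)
      if (specific) {
        g <- taxa[sample.int(nrow(taxa), 1L)]
        k <- k + 1L
        prot[[k]] <- data.table::data.table(
          id = sprintf("%s|%s", g$genome, gid), genome = g$genome,
          genus = g$genus, class = g$class, group = gid,
          seq = paste(sample(AA_ALPHABET20, len, replace = TRUE),
                      collapse = ""))
        next
      }
      root <- sample(AA_ALPHABET20, len, replace = TRUE)
      # patchy loss: drop copies in a random subset, keeping >= 1 genome
      lost <- taxa$genome[stats::runif(nrow(taxa)) < loss_frac]
      if (length(lost) == nrow(taxa)) lost <- lost[-1]
      for (cl in unique(taxa$class)) {
        cls_anc <- mutate_protein(root, d_x / 2)
        for (gn in unique(taxa[class == cl]$genus)) {
          gen_anc <- mutate_protein(cls_anc, (d_c - d_g) / 2)
          for (gm in setdiff(taxa[class == cl & genus == gn]$genome, lost)) {
            k <- k + 1L
            prot[[k]] <- data.table::data.table(
              id = sprintf("%s|%s", gm, gid), genome = gm, genus = gn,
              class = cl, group = gid,
              seq = paste(mutate_protein(gen_anc, d_g / 2), collapse = ""))
          }
        }
      }
    }
    proteins <- data.table::rbindlist(prot[seq_len(k)])

    genomes_dna <- lapply(taxa$genome, function(gm) {
      rows <- proteins[genome == gm]
      seqs <- character(0)
      genes <- list()
      pos <- 0L
      for (i in seq_len(nrow(rows))) {
        spacer <- random_dna(sample(200:500, 1L), 0.45)
        dna <- back_translate(seq_chars(rows$seq[i]), codons)
        strand <- sample(c("+", "-"), 1L)
        gene_on_genome <- if (strand == "+") dna else revcomp(dna)
        start <- pos + nchar(spacer)
        genes[[i]] <- data.table::data.table(
          protein_id = rows$id[i], start = start,
          end = start + nchar(dna), strand = strand)
        seqs <- c(seqs, spacer, gene_on_genome)
        pos <- start + nchar(dna)
      }
      list(seq = paste(seqs, collapse = ""),
           genes = data.table::rbindlist(genes))
    })
    names(genomes_dna) <- taxa$genome

    protein_db(proteins, taxonomy = taxa, genomes_dna = genomes_dna)
  })
}

#' Construct a reference protein database
#'
#' @param proteins `data.table`/`data.frame` with columns `id`, `genome`,
#'   `genus`, `class`, `group` (ortholog group id; `NA` allowed), `seq`.
#' @param taxonomy optional `data.frame(genome, genus, class)`; derived from
#'   `proteins` when missing.
#' @param genomes_dna optional named list of genome DNA (see
#'   [simulate_protein_families()]).
#' @return a `ProteinDB` object.
#' @export
protein_db <- function(proteins, taxonomy = NULL, genomes_dna = NULL) {
  proteins <- data.table::as.data.table(proteins)
  assert_that(nrow(proteins) > 0, "protein database is empty")
  assert_that(all(c("id", "genome", "genus", "class", "seq") %in%
                    names(proteins)), "missing protein columns")
  if (!"group" %in% names(proteins)) proteins$group <- NA_character_
  if (is.null(taxonomy))
    taxonomy <- unique(proteins[, list(genome, genus, class)])
  structure(list(proteins = proteins,
                 taxonomy = data.table::as.data.table(taxonomy),
                 genomes_dna = genomes_dna),
            class = "ProteinDB")
}

#' @export
print.ProteinDB <- function(x, ...) {
  cat(sprintf("ProteinDB: %d proteins, %d genomes, %d genera, %d classes\n",
              nrow(x$proteins), length(unique(x$proteins$genome)),
              length(unique(x$proteins$genus)),
              length(unique(x$proteins$class))))
  invisible(x)
}

#' Drop one genome from a protein database (leave-one-out)
#' @param db a `ProteinDB`.
#' @param genome genome label to remove.
#' @return a `ProteinDB` without that genome's proteins.
#' @export
drop_genome <- function(db, genome) {
  drop_label <- genome
  keep_rows <- which(db$proteins$genome != drop_label)
  assert_that(length(keep_rows) > 0, "dropping '%s' empties the database",
              drop_label)
  protein_db(db$proteins[keep_rows],
             taxonomy = db$taxonomy[which(db$taxonomy$genome != drop_label)],
             genomes_dna = db$genomes_dna)
}
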