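# Ortholog-threshold classifier: threshold matrix, translated search, hit
# merging, hierarchical assignment, LCA, rRNA screen, FP validation.

aa_mutate_exact <- function(seq, n_subs, seed) {
  withr::with_seed(seed, {
    ch <- strsplit(seq, "")[[1]]
    pos <- sample(length(ch), n_subs)
    pool <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
              "M", "F", "P", "S", "T", "W", "Y", "V")
    for (p in pos) ch[p] <- sample(setdiff(pool, ch[p]), 1)
    paste(ch, collapse = "")
  })
}

random_protein <- function(len, seed) {
  withr::with_seed(seed, paste(sample(c("A", "R", "N", "D", "C", "Q", "E",
                                        "G", "H", "I", "L", "K", "M", "F",
                                        "P", "S", "T", "W", "Y", "V"),
                                      len, replace = TRUE), collapse = ""))
}

test_that("threshold matrix: elongation-factor-style fixture and defaults", {
  base <- random_protein(476, 101)
  genus_mate <- aa_mutate_exact(base, 114, 102)     # 362/476 = 76.05%
  class_mate <- aa_mutate_exact(substr(base, 1, 434), 226, 103) # ~47.9%
  pr <- data.table::data.table(
    id = c("Olu|ef1a", "Ota|ef1a", "Mic|ef1a", "Olu|orphan"),
    genome = c("Olu", "Ota", "Mic", "Olu"),
    genus = c("Ostreo", "Ostreo", "Micro", "Ostreo"),
    class = "Mamiello",
    group = c("ef1a", "ef1a", "ef1a", "orphan"),
    seq = c(base, genus_mate, class_mate, random_protein(150, 104)))
  db <- protein_db(pr)
  tm <- build_threshold_matrix(db)
  row <- tm[tm$protein_id == "Olu|ef1a"]
  # within-genus pair aligns gap-free over the full 476 columns
  expect_equal(row$l_min_genus, 476)
  expect_equal(row$i_min_genus, 362 / 476, tolerance = 1e-6)
  # within-class thresholds come from the diverged truncated mate
  expect_lt(row$i_min_class, row$i_min_genus)
  expect_equal(row$l_min_class, 434, tolerance = 6 / 434)
  expect_equal(row$i_min_class, 0.48, tolerance = 0.05 / 0.48)
  # invariant: class thresholds never exceed genus thresholds
  both <- tm[!tm$specific & !is.na(tm$i_min_genus)]
  expect_true(all(both$i_min_class <= both$i_min_genus + 1e-12))
  # single-genome gene -> SPECIFIC defaults
  orow <- tm[tm$protein_id == "Olu|orphan"]
  expect_true(orow$specific)
  expect_equal(orow$i_min_genus, 0.80)
  expect_equal(orow$l_min_genus, 50)
  expect_error(build_threshold_matrix(
    protein_db(pr[0])), "empty")
})

test_that("threshold matrix equals brute-force min over ortholog pairs", {
  db <- toy_db()
  tm <- toy_matrix()
  pr <- db$proteins
  cnt <- table(pr$group)
  fam <- names(cnt)[cnt == 4][1]
  rows <- pr[pr$group == fam]
  for (i in seq_len(nrow(rows))) {
    mates <- rows[-i]
    same_genus <- mates$genus == rows$genus[i]
    st <- lapply(mates$seq, protein_pair_identity, a = rows$seq[i])
    got <- tm[tm$protein_id == rows$id[i]]
    expect_equal(got$i_min_genus, min(vapply(st[same_genus], `[[`, 0,
                                             "identity")))
    expect_equal(got$i_min_class, min(vapply(st, `[[`, 0, "identity")))
    expect_equal(got$l_min_class, min(vapply(st, `[[`, 0, "length")))
  }
})

test_that("translated_search finds exact and reverse-complement matches", {
  prot <- random_protein(120, 7)
  pr <- data.table::data.table(id = "G1|p1", genome = "G1", genus = "g",
                               class = "c", group = "f1", seq = prot)
  db <- protein_db(pr)
  codons <- getFromNamespace("codon_table", "picometa")()
  dna <- withr::with_seed(8, paste(vapply(strsplit(prot, "")[[1]],
    function(a) sample(codons[[a]], 1), ""), collapse = ""))
  hits <- translated_search(dna, db, query_id = "q")
  top <- hits[which.max(hits$score)]
  expect_equal(top$frame, 1)
  expect_equal(top$matches, 120)
  expect_equal(top$cols, 120)
  expect_equal(c(top$qstart, top$qend), c(1, 360))

  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
  hits_rc <- translated_search(rc, db, query_id = "q")
  top_rc <- hits_rc[which.max(hits_rc$score)]
  expect_lt(top_rc$frame, 0)
  expect_equal(top_rc$matches, 120)
  expect_equal(top_rc$score, top$score)

  expect_error(translated_search("AC", db), "codon")
  # stop-codon-rich frames never crash
  expect_s3_class(translated_search(strrep("TGA", 30), db), "data.frame")
})

test_that("translated_search scores match the full DP oracle", {
  suppressMessages(utils::data("BLOSUM62", package = "Biostrings",
                               envir = environment()))
  for (s in 1:5) {
    prot <- random_protein(60, 200 + s)
    near <- aa_mutate_exact(prot, 8, 300 + s)
    pr <- data.table::data.table(id = "G1|p", genome = "G1", genus = "g",
                                 class = "c", group = "f", seq = near)
    db <- protein_db(pr)
    codons <- getFromNamespace("codon_table", "picometa")()
    dna <- withr::with_seed(400 + s, paste(vapply(strsplit(prot, "")[[1]],
      function(a) sample(codons[[a]], 1), ""), collapse = ""))
    hits <- translated_search(dna, db, query_id = "q", min_score = 20)
    frame_aa <- getFromNamespace("translate_frame", "picometa")(dna, 1L)
    expect_equal(max(hits$score),
                 sw_score_oracle(near, frame_aa, BLOSUM62))
  }
})

test_that("merge_hits: disjoint, overlapping and single-hit cases", {
  mk <- function(qs, qe, matches, score)
    data.table::data.table(query_id = "q", subject_id = "s", frame = 1,
                           qstart = qs, qend = qe, sstart = 1, send = 1,
                           matches = matches, cols = (qe - qs + 1) / 3,
                           score = score)
  # two disjoint hits covering 100 aa and 50 aa
  two <- rbind(mk(1, 300, 90, 100), mk(601, 750, 40, 50))
  expect_equal(merge_hits(two)$L, 150)
  # overlap by 20 aa: 100 + 50 - 20
  ovl <- rbind(mk(1, 300, 90, 100), mk(241, 390, 40, 50))
  expect_equal(merge_hits(ovl)$L, 130)
  # single hit keeps its own identity and length
  one <- mk(1, 300, 90, 100)
  m1 <- merge_hits(one)
  expect_equal(m1$L, 100)
  expect_equal(m1$I, 0.9)
  expect_error(merge_hits(one[0]), "empty")
  expect_error(merge_hits(rbind(one, data.table::copy(one)[
    , subject_id := "other"])), "one query-subject")
})

test_that("assign_taxon follows the genus -> class -> default hierarchy", {
  pr <- data.table::data.table(
    id = c("Olu|ef1a", "Olu|orphan"), genome = "Olu",
    genus = "Ostreo", class = "Mamiello", group = c("ef1a", "orphan"),
    seq = c(random_protein(476, 1), random_protein(100, 2)))
  db <- protein_db(pr)
  tm <- data.table::data.table(
    protein_id = c("Olu|ef1a", "Olu|orphan"),
    specific = c(FALSE, TRUE),
    i_min_genus = c(0.76, 0.80), l_min_genus = c(476L, 50L),
    i_min_class = c(0.48, 0.80), l_min_class = c(434L, 50L))
  merged <- function(I, L, subject = "Olu|ef1a")
    data.table::data.table(query_id = "q", subject_id = subject,
                           L = L, I = I, score = 100, n_hits = 1)
  expect_equal(assign_taxon(merged(0.80, 500), tm, db)$level, "genus")
  expect_equal(assign_taxon(merged(0.80, 500), tm, db)$taxon, "Ostreo")
  a2 <- assign_taxon(merged(0.60, 500), tm, db)
  expect_equal(a2$level, "class")
  expect_equal(a2$taxon, "Mamiello")
  # below class thresholds but above the default rule -> best-hit genus
  expect_equal(assign_taxon(merged(0.85, 60), tm, db)$level, "bbh-default")
  # SPECIFIC protein failing both defaults -> unassigned
  expect_equal(assign_taxon(merged(0.79, 49, "Olu|orphan"), tm, db)$level,
               "unassigned")
  # soundness: a genus call re-satisfies its thresholds
  a <- assign_taxon(merged(0.80, 500), tm, db)
  expect_true(a$I >= tm$i_min_genus[1] && a$L >= tm$l_min_genus[1])
})

test_that("raising thresholds never increases genus-level assignments", {
  db <- toy_db()
  tm <- toy_matrix()
  idx <- protein_kmer_index(db)
  g <- db$genomes_dna[["Gen2_sp1"]]$seq
  frags <- withr::with_seed(5, {
    st <- sample.int(nchar(g) - 600, 30)
    stats::setNames(substring(g, st, st + 599), paste0("f", 1:30))
  })
  base <- classify_queries(frags, db, tm, index = idx)
  stricter <- data.table::copy(tm)
  stricter$i_min_genus <- pmin(1, stricter$i_min_genus + 0.05)
  strict <- classify_queries(frags, db, stricter, index = idx)
  expect_lte(sum(strict$level == "genus"), sum(base$level == "genus"))
  # in-db fragments overwhelmingly land on the right genus
  assigned <- base[base$level %in% c("genus", "bbh-default")]
  expect_gte(mean(assigned$taxon == "Genus2"), 0.95)
})

test_that("lca_assign implements score filters, LCA and min-support", {
  tree <- taxonomy_tree(data.frame(
    taxon = c("root", "Eukaryota", "Bacteria", "Mamiello", "Ostreo",
              "Pelagibacter"),
    parent = c(NA, "root", "root", "Eukaryota", "Mamiello", "Bacteria")))
  hit <- function(q, tx, sc) data.table::data.table(query_id = q,
                                                    taxon = tx, score = sc)
  # all kept hits on one taxon (min_support 1 to isolate the LCA rule)
  h1 <- rbind(hit("q1", "Ostreo", 100), hit("q1", "Ostreo", 95),
              hit("q1", "Mamiello", 50))  # below top-10% band
  expect_equal(lca_assign(h1, tree, min_support = 1)$taxon, "Ostreo")
  # eukaryote/bacterium split resolves to the root
  h2 <- rbind(hit("q2", "Ostreo", 80), hit("q2", "Pelagibacter", 78))
  expect_equal(lca_assign(h2, tree, min_support = 1)$taxon, "root")
  # hits below min_score leave the query unassigned
  expect_true(is.na(lca_assign(hit("q3", "Ostreo", 20), tree,
                               min_support = 1)$taxon))
  # 4 queries on a taxon with min_support 5 -> raised to parent
  h4 <- data.table::rbindlist(lapply(1:4, function(i)
    hit(paste0("s", i), "Ostreo", 90)))
  out <- lca_assign(h4, tree, min_support = 5)
  expect_true(all(out$taxon == "Mamiello" | out$taxon == "root"))
  expect_error(lca_assign(hit("q", "Martian", 99), tree), "Martian")
})

test_that("screen_rrna keeps only hits longer than the length floor", {
  set.seed(31)
  ssu <- paste(sample(c("A", "C", "G", "T"), 1200, replace = TRUE),
               collapse = "")
  spacer <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")
  contigs <- c(full = paste0(spacer(300), ssu, spacer(200)),
               frag = paste0(spacer(250), substr(ssu, 1, 150), spacer(250)),
               none = spacer(900))
  hits <- screen_rrna(contigs, c(SSU = ssu), min_hit_len = 200)
  expect_equal(hits$contig, "full")
  expect_gt(hits$length, 200)
  # exhaustive count oracle at a permissive floor
  hits50 <- screen_rrna(contigs, c(SSU = ssu), min_hit_len = 50)
  expect_equal(nrow(hits50), sum(c(1350, 150) > 50))
})

test_that("leave-one-out control: self-matches yield no false positives", {
  db <- toy_db()
  v <- validate_false_positives(db, "Gen1_sp1", fragment_len = 500,
                                n_fragments = 40, seed = 3,
                                keep_in_db = TRUE)
  expect_lte(v$fp_bbh, 0.05)
  expect_error(validate_false_positives(db, "Gen1_sp1",
                                        fragment_len = 10^7), "fragment_len")
})

test_that("tabular hit import recomputes matches and feeds merge_hits", {
  tab <- data.frame(q = "q1", s = "G1|p", pident = 90, length = 100,
                    mism = 10, gapo = 0, qstart = 1, qend = 300,
                    sstart = 1, send = 100, evalue = 1e-50, bitscore = 180)
  hits <- import_tabular_hits(tab)
  expect_equal(hits$matches, 90)
  m <- merge_hits(hits)
  expect_equal(m$L, 100)
  expect_equal(m$I, 0.9)
  expect_error(import_tabular_hits(tab[, 1:5]), "12")
})
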