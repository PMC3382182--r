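---
title: "Methods: models, parameters and design choices in picometa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in picometa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`picometa` re-implements, as reusable and tested components, the analytics
needed for a metagenome obtained from a *single dominant picoeukaryote
population*: cells sorted by flow cytometry, amplified by multiple
displacement amplification (MDA), sequenced with a long-read
pyrosequencing-style chemistry, and analysed against a closely related
reference genome. The package covers five concerns:

1. **Synthetic data** — generators for reference genomes, genotype
   mixtures, contaminant-style protein databases and MDA-biased read sets,
   all with complete ground-truth tracking;
2. **Reference mapping** — read trimming, seed-and-extend mapping,
   per-chromosome coverage/consensus analytics and the GC-coverage
   correlation;
3. **Taxonomic assignment** — the ortholog-threshold translated-search
   classifier, with hit merging, hierarchical genus/class/default
   assignment, a minimal LCA implementation, rRNA screening and
   leave-one-out false-positive validation;
4. **Population diversity** — filtered variant calls, minimum-haplotype
   decomposition and rRNA intron genotyping;
5. **Similarity reports** — coverage-masked multi-genome identity with a
   CDS / non-CDS split, gene-panel similarity and run-level tables.

# The synthetic world

The generator defaults describe a scaled-down version of the kind of
dataset the analytics were designed for. They were chosen once, from the
stated properties of such data, and are not tuned against test outcomes.

## Reference genomes

`simulate_reference()` builds chromosomes segment by segment as i.i.d.
base draws at a target GC. The default plan
(`default_reference_plan()`) is a ~1.1 Mbp genome with:

* ten "standard" nuclear chromosomes at 47.0-48.9% GC (GC homogeneity is
  the norm for such genomes, with only slight spread between
  chromosomes);
* one large *outlier* chromosome with a tri-partite base composition —
  47% / 39% / 47% GC segments — mimicking low-GC outlier chromosomes with
  atypical middle regions;
* one small low-GC outlier chromosome (42%);
* two organelles (chloroplast-like and mitochondrion-like) at 40-41% GC.

A single rRNA operon (SSU 1800 bp, ITS 546 bp, LSU 3300 bp = 5646 bp,
matching the size of the real operon analysed) is placed on a designated
chromosome; non-overlapping CDS features of 600-1800 bp cover roughly
60% of nuclear sequence, which is what gene-dense picoeukaryote genomes
look like.

For any segment of at least 50 kbp the realised GC is guaranteed (and
tested) to fall within 1.5 percentage points of its target; this follows
from the binomial standard deviation at that length, so the contract is a
law-of-large-numbers statement, not a calibration.

## Genotype mixtures

`plant_genotypes()` derives genotype genomes from the reference by
independent substitutions at `snp_rate` (0-0.2), optional explicit
substitutions, and optional rRNA intron insertions. Intron alleles use
deterministic sequences keyed by feature and length, so every genotype
carrying "the" 433 bp SSU intron carries the same sequence — as a real
population would. The stated mixture frequencies exercised by tests and
benchmarks are 85/15 and 59/41, the two-genotype proportions such data
actually shows, with 1-3 genotypes per sample.

## MDA amplification bias

No quantitative law for MDA bias exists; the generator therefore uses the
smallest mechanism that reproduces the two qualitative phenomena the
analytics must cope with: long-range coverage waves along chromosomes and
a positive GC-coverage association across chromosomes.

The per-base read-start weight is

```
w(x) = abundance * exp(F(x) + gc_slope * (GC_1kb(x) - GC_genome)) * copy_number
```

* `F` — a lognormal *anchor field*: i.i.d. normal draws with standard
  deviation `log_sd` (default 1.2) at anchors every `anchor_spacing`
  (default 5 kbp), linearly interpolated. Two parameters reproduce
  coverage waves of realistic wavelength and amplitude.
* GC effect — `gc_slope` (default 4 per unit GC deviation) applied in
  1 kbp windows: a chromosome 9 GC points below the genome mean is
  under-amplified by about `exp(-0.36)` (factor 0.7), enough to make
  low-GC outliers visibly under-covered without drowning the anchor
  noise. The value is a free knob, set once for qualitative realism.
* `organelle_copy_number` (default 20) multiplies organelle weights,
  emulating multi-copy organelle genomes, which show high depth despite
  low GC.

Weights are normalised *within* each genotype, so read counts per genotype
stay multinomial around the stated abundances (a tested conservation
invariant); the anchor field redistributes coverage along a genome but
does not transfer reads between genotypes.

Read lengths follow a truncated lognormal parameterised by
`(min, max, mean, shape)`, default `(40, 2044, 420, 0.5)` — the documented
range and mean of half-plate pyrosequencing runs, with the long right
tail that `shape = 0.5` produces. Sequencing errors are substitutions
only at 0.5% by default; homopolymer indel modelling was deliberately
left out because no downstream component consumes it. Quality strings are
constant Q30, since only trimming reads qualities.

## Protein families

`simulate_protein_families()` evolves amino-acid families down a fixed
class → genus → genome tree with per-level rates chosen so mean
within-genus divergence ≈ `divergence$genus` (default 0.10) and
within-class ≈ `divergence$class` (default 0.40). Two kinds of
incompleteness are planted because they drive classifier behaviour:

* *genome-specific families* (`specific_frac`, default 0.15) — present in
  a single genome, exercising the 80% / 50 aa default rule;
* *patchy loss* (`loss_frac`, default 0.15) — a shared family randomly
  missing from some genomes. In leave-one-out validation these are the
  main source of confident wrong-genus best hits: when the sister species
  lost its copy, the best hit comes from the wrong genus at class-level
  divergence.

Genes are back-translated with random synonymous codons and embedded in
random intergenic spacers to give each genome a nuclear DNA sequence with
tracked gene coordinates.

## What the generator does *not* emulate

Chimeric MDA artifacts, paired-end layouts, homopolymer indels,
repeat families, paralogy, and real codon usage. A green test therefore
establishes that the analytics implement their stated rules and recover
planted structure under realistic noise — not that they are robust to
every artifact of real amplified libraries.

# Reference mapping

`map_reads()` is a greedy seed-and-extend mapper: exact 14-mer seeds at
~60 bp spacing over both orientations, diagonal voting per
(chromosome, offset), then extension. Because the error model and the
genotype model are substitution-only, the first extension attempt is an
ungapped comparison at the voted diagonal; banded global-local dynamic
programming (affine gaps, match 2 / mismatch -3 / open 5 / extend 2) is
the fallback. Alignments are reported only at identity ≥ 0.90 over ≥ 40
columns — mirroring standard long-read assembler defaults — and each read
gets one best location, ties broken by lowest (chromosome, position).
These are the coordinates everything downstream shares.

Numerical conventions, stated once and used everywhere:

* coordinates are 0-based half-open internally, 1-based in reports and
  SAM;
* *coverage fraction* = share of reference bases with depth ≥ 1;
  *coverage depth* = mean of the depth array; depth counts
  reference-spanning columns (M and D);
* consensus is majority-per-column, reference-projected: ties and
  zero-coverage columns fall back to the reference base (uncovered
  columns flagged). This keeps consensus coordinates identical to
  reference coordinates, which is what makes the three-way alignment of
  the similarity module columnwise-exact and removes any need for a
  multiple aligner;
* *identical sites %* is computed over read-covered columns only. This
  matches the behaviour of reported tables in which sparsely covered
  chromosomes show high identity: uncovered columns are unknown, not
  mismatched;
* the GC-coverage statistic is tie-aware Spearman rho with a one-sided
  p-value from the t approximation at n - 2 degrees of freedom, computed
  on **coverage fraction**. Both choices were validated against the
  published per-chromosome table: fraction with a one-sided test
  reproduces both printed coefficients and p-values, depth does not. The
  two-sided p is also returned.

# Taxonomic assignment

The classifier follows the two-step ortholog-threshold design.

**Thresholds.** For each protein with orthologs, `I_min` / `L_min` are
the minima of identity and aligned length over end-gap-free global
(overlap) alignments against ortholog-group members of other genomes,
restricted to the protein's genus and to its class. Identity uses aligned
columns excluding end gaps as the denominator, with internal gaps counted
as mismatch columns. Single-genome genes are flagged SPECIFIC with the
(0.80, 50 aa) defaults. BLOSUM62 with gap open 10 / extend 0.5 is used
for these global alignments; the original method does not name its
aligner, so this is the package's choice, applied consistently to both
threshold building and validation.

**Search.** Six-frame translation (cached codon lookup; stops become
`*`), amino-acid 5-mer seeding against a precomputed database index, and
vectorised Smith-Waterman extension (BLOSUM62, open 11 / extend 1,
the standard translated-search parameterisation). Raw scores below
`min_score` (default 35, reusing the LCA floor) are dropped. Pre-computed
12-column tabular hits can be imported instead; identity is then
recomputed from `pident * length`.

**Merging.** All local hits of one query-subject pair merge into one
non-redundant alignment over the union of query positions (nucleotide
scale, reported in amino acids). Overlapping positions count once and
inherit the match density of the highest-scoring hit covering them (ties:
lowest query start, then end — the same rule the test oracle uses). `L`
is the union size / 3; `I` the owned-match total over the union.

**Assignment.** The best hit is the subject with the highest merged score
(ties: lexicographically smallest subject id; the original description is
silent on both, so the package fixes them deterministically). Then:
genus if `I ≥ I_min_genus` and `L ≥ L_min_genus`; else class on the class
thresholds; else the best hit's genus under the 80% / 50 aa default; else
unassigned. Because `L_min` is measured on the merged query cover,
fragments shorter than the ortholog alignment length legitimately fall
through to the default rule — short-fragment assignments are
expected to be `bbh-default`, not `genus`.

**Validation.** `validate_false_positives()` removes one genome, samples
random fragments from its DNA, and reports the wrong-genus rate for the
raw best hit (`fp_bbh`) and for the filtered assignment (`fp_filtered`).
Class-level assignments are not counted as errors (only wrong-genus
calls are; this is the reading adopted for the "false positive" notion,
flagged as a sensitivity choice). The denominator is fragments with at
least one hit.

**LCA.** `lca_assign()` keeps hits with score ≥ 35 within 10% of the
per-query best, assigns the lowest common ancestor, and then repeatedly
raises queries on taxa with fewer than 5 assigned queries to the parent
(deepest taxon first, root never raised) — the standard
min-score / top-percent / min-support parameterisation.

# Population diversity

**Variant calls.** A non-reference allele is called iff depth ≥ 5, allele
count ≥ 2 and frequency ≥ 15% — the documented triple filter for
reporting single-nucleotide variability, kept as `call_variants()`
defaults.

**Minimum haplotypes.** `min_haplotypes()` asks for the smallest number
of genotypes explaining recurrent co-occurring changes. Candidate
positions are those passing the variant filter, with the frequency floor
lowered to 5% *for discovery only*: the decomposition's own recurrence
rule (≥ 2 reads sharing ≥ 2 changes) provides specificity, and a hard
15% floor would censor a genotype segregating at exactly 15% (binomial
noise puts its observed frequency below the cutoff about half the time).
Reads covering at least `min_shared_positions` variant positions are
informative and are grouped by their exact (position, allele) signature.
Groups are declared haplotypes most-complete-first; a group whose
signature is a subset of an already-declared haplotype joins it rather
than founding a new genotype (otherwise reads that merely fail to span
every variant position would inflate the count). Reads are then assigned
to the haplotype consistent with them at every covered variant position;
inconsistent reads (isolated differences are treated as sequencing
error) fold into the nearest haplotype by signature distance, ties
favouring the reference. Frequencies are computed over informative reads
only. One-position genotypes — which the recurrence rule cannot
distinguish from recurrent sequencing error — are deliberately absorbed;
this is the package's resolution of a genuinely ambiguous rule, and the
Fig-3-style test pins the resulting behaviour.

**Intron genotyping.** `call_introns()` aligns each read (both
orientations) to an intron-bearing and an intron-free version of the
locus. A read is informative only if its alignment spans an exon-intron
junction with ≥ 20 aligned bases on each side (the flank value is the
package's choice; nothing shorter can anchor a junction reliably at the
0.5% error rate), and votes for the variant with the strictly higher
score. The summary reports the intron+ fraction among informative reads.

# Similarity reports

Consensuses are reference-projected, so `anchored_align()` is columnwise
by construction. `mask_low_coverage()` retains a column iff *both*
samples reach `min_depth` (default 10×) there. `identity_report()`
computes three-way and pairwise identical-site percentages, split into
CDS and non-CDS columns by the annotation (a column inside any CDS
feature on either strand is CDS); totals are length-weighted means of
per-chromosome values, and every totals row is defined as the
recomputation from its per-chromosome rows — reports cannot drift from
their own parts (published tables of this kind contain at least one
total that does not equal its column sum; the package's totals are
defined to make that impossible).

`gene_panel_similarity()` searches each gene against all contigs by
local alignment and reports the best contig above a raw-score floor
(default 100, a stand-in for the e-value cutoff of a database search
engine, which the internal search does not compute) with percent identity
over the aligned region.

# Known limitations

* The mapper is substitution-oriented; reads spanning large novel
  insertions (e.g. intron junctions relative to an intron-free reference)
  are expected to fail mapping and are handled by the dedicated intron
  caller instead.
* The translated search is a miniature: no E-values, no composition-based
  statistics, amino-acid 5-mer seeding only. It is adequate for databases
  of hundreds of proteins, not millions.
* The LCA implementation handles one tree, one rank relation; it is a
  functional stand-in for a full metagenomics binner, not a replacement.
* Published per-chromosome coverage values, gene-panel identities and raw
  false-positive percentages from the motivating study depend on deposited
  reads and external genomes; the package ships the printed summary
  tables and checks everything that can be recomputed from them, while
  the synthetic property suites cover the algorithmic content.
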