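---
title: "Detecting circular RNAs and C/D box sRNAs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting circular RNAs and C/D box sRNAs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circsrna)
```

## The biological question

Archaea circularize several classes of small RNAs. tRNA introns and rRNA
processing intermediates are closed by the RtcB ligase after
bulge-helix-bulge cleavage, while C/D box sRNAs — the small guide RNAs that
direct 2′-O-methylation of rRNA and tRNA — are circularized by the
ATP-dependent RNA ligase (Rnl). Deleting the Rnl gene in a hyperthermophilic
archaeon such as *Thermococcus kodakarensis* therefore removes circular C/D
box sRNAs while leaving RtcB-dependent circles untouched. `circsrna`
implements the computational side of that experiment: finding circular-RNA
junction evidence in RNA-Seq reads, aggregating it into candidate loci,
comparing a wild-type (WT) and a knockout (KO) sample to call depletion,
and annotating candidates as C/D box sRNAs with a terminal-stem
circularizability prediction.

## The junction model

A covalently closed circle has no ends; a read sequenced across its closure
point contains the transcript's 3′ end followed by its 5′ end. Against the
linear reference genome such a read splits into two segments that match
exactly, on the same strand, but in *inverse genomic order*: the read's
first part lies downstream of its second part. `find_circular_junctions()`
enumerates every split of a read into two parts of at least
`min_segment_len` (default 20 nt, so a 51-nt read allows splits 20–31),
places both parts by exact match on both strands
(`genome_index()`/`locate_matches()`), and emits a junction
`(circ_start, circ_end)` — the genomic interval the circle spans, in
plus-strand coordinates with `circ_start ≤ circ_end` — for every
inverse-order placement pair.

Numerical and policy choices, all of which are deliberate and tested:

* **Exact matching.** No mismatches are tolerated. This makes the search a
  well-defined string problem with a brute-force oracle, at the cost of
  losing reads carrying sequencing errors (quantified in the test suite
  with an error-rate simulation; inputs are assumed quality-trimmed).
* **Linear veto.** A read that also places contiguously full-length
  anywhere in the genome is never reported, even if a split interpretation
  exists: inverse order is the defining signature and the contiguous
  interpretation is more parsimonious.
* **Ambiguity.** At a given split, if both parts place at more than one
  genomic position the split is discarded (repeat-induced junction
  combinatorics); pairs are emitted only when at least one part places
  uniquely. We apply this rule per split rather than discarding the whole
  read, which is equivalent on repeat-free genomes and strictly limits
  what a single repeat-contaminated split can suppress.
* **Per-read deduplication.** Micro-homology at the closure point makes
  several splits of one read describe the same junction; one hit is
  emitted per distinct junction per read (leftmost split kept), so
  downstream counts are per read.
* **Minus strand.** Minus-strand hits are computed in the plus-strand
  frame (the reverse complement of a segment matches the forward genome)
  with the inverse-order test mirrored, so reverse-complementing every
  read leaves the junction multiset invariant with strand labels flipped.

`detect_sample()` runs the search over a whole read set. Identical read
sequences necessarily yield identical hits, so results are memoized per
unique sequence — an exactness-preserving optimization that matters because
deep small-RNA libraries are dominated by duplicate reads.

## Aggregation: clusters, representatives, filters

Sequencing noise and junction micro-homology scatter raw junctions over a
few nucleotides. `cluster_junctions()` groups raw junctions whose two
endpoints both lie within `junction_group_tolerance` (default 5 nt) of a
representative, using greedy count-weighted seeding: the most-supported
unassigned junction becomes the representative (ties: smaller start, then
smaller end) and absorbs its neighborhood. We chose seeded clustering over
single-linkage because single-linkage chains are unbounded — two junctions
11 nt apart could end up grouped through an intermediate — whereas the
seeded rule guarantees every member is within tolerance of its
representative, and the representative is the modal junction, which is what
gets reported. Clustering is deterministic and input-order invariant.

`predicted_length()` is the inclusive span `circ_end − circ_start + 1`.
`filter_clusters()` applies the library-type filters: total-RNA candidates
need ≥ `min_count_total_rna` (100) circular reads; small-RNA candidates
need ≥ `min_count_small_rna` (20) and a predicted length ≤
`max_predicted_len` (10 kb). The length filter deliberately applies only to
small-RNA libraries, where a multi-kilobase "circle" is almost certainly a
clustering artifact of the short-insert protocol. Failed candidates are
retained with a reason rather than dropped, because the WT/KO comparison
needs sub-threshold KO counts.

## The WT/KO comparison

`compare_samples()` anchors on WT candidates that passed filters and
matches each to KO evidence within the clustering tolerance (including KO
clusters that failed filters — a depleted locus is precisely one whose KO
evidence collapses below threshold). The depletion rule is a KO/WT
circular-read ratio below `depletion_ratio`, default 0.05. The published
catalog packaged with this package (`tk_circ_catalog()`) pins this choice:
the 24 loci reported lost or strongly reduced in the knockout have ratios
of at most ≈ 0.044, while the seven retained loci (the tRNA-Trp intron,
three rRNA-derived circles, and three long mRNA-derived circles) sit at
≈ 0.42 or higher, so any threshold in roughly [0.05, 0.40] reproduces the
published split; 0.05 is the conservative end. A locus with zero WT reads
is `not_detected_in_wt` and gets no ratio.

Expression comparison follows the published scatter-plot conventions:
`compute_rpkm()` is `count × 10⁹ / (total_mapped × length)` (computed in
double precision; the integer product overflows 32 bits at library scale),
RPKM below `rpkm_floor` (1) is stored as 0, records below `rpkm_min_either`
(2) in both samples are omitted, and `classify_fold_change()` uses the
strict ">2-fold" boundary — KO exactly double WT is *unchanged*. A floored
zero on one side with the other side ≥ 2 satisfies the strict inequality
and is called directly; the classification is antisymmetric under swapping
the samples. `compute_coverage()` builds per-base depth tracks from
contiguous full-length placements (multi-placed reads fractionally, 1/n)
and can rescale a KO track by total placed reads to the WT scale, the
convention used for coverage-hole comparisons around processed rRNA
segments.

## C/D box annotation and the terminal stem

`scan_cdbox_motifs()` reports every match of the C-box consensus RUGAUGA
(R = A/G; IUPAC matching via Biostrings) and the D-box consensus CUGA,
overlaps included. `annotate_locus()` extracts a candidate's strand-aware
sequence and applies a positional rule: a C box starting in the 5′ third
and a D box ending in the 3′ third make the locus a C/D box sRNA; interior
hits between them are assigned C′/D′. The thirds rule is our own — box
positions in the literature are drawn, not defined — and is the natural
formalization of "C near the 5′ end, D near the 3′ end" at the 61–71 nt
scale of these RNAs.

Circularization by an ATP-dependent ligase requires the two ends to meet;
C/D box sRNAs that circularize can pair their termini into a short stem.
`terminal_stem_pairs()` scores this as the number of consecutive
complementary pairs aligning the 5′-terminal window against the reversed
3′-terminal window, outermost first, stopping at the first non-pair — a
gapless integer count, not a thermodynamic fold. A folding engine would
demand choices (energy model, temperature — these organisms grow at 85 °C)
that the downstream rule, a simple "three or more pairings" threshold
(`classify_circularizable()`), does not need. G:U wobble pairs count by
default, as in any RNA duplex; note that wobble pairing is *not* preserved
under reverse complement (G:U maps to C:A), so only the Watson–Crick score
is strand-symmetric, and the package's invariance tests use
`count_gu = FALSE`. The window is 8 nt by default: terminal stems of these
sRNAs are short and GC-rich, and 8 comfortably bounds the reported pairing
counts while staying inside the shortest (61 nt) loci.

## What the simulator emulates — and what it does not

`simulate_genome()` plants, in a random background (default 100 kb, one
record), non-overlapping loci on random strands:

* **Circular C/D-box-like loci** (default 20, lengths 61–71 nt): a GC-rich
  terminal stem with 3–6 designed Watson–Crick pairings terminated by a
  forced non-pair (so the designed count is exact and verified with
  `terminal_stem_pairs()` at construction), a C box near the 5′ end, a D
  box near the 3′ end.
* **Non-circular C/D loci** (default 10): identical layout with the stem
  broken to ≤ 2 pairings — the structural dichotomy that separates
  circularized from non-circularized C/D box sRNAs.
* **Linear genes** (default 50, 200–600 nt) of plain random sequence.
* Optionally one **rRNA-like locus** whose internal 40-nt segment is
  excluded from read generation, emulating the coverage hole left by a
  processed helix excision.

Every locus's terminal arms (the junction arm sequences, read length − 20)
are checked to occur exactly once in the genome across both strands,
regenerating on collision, so planted junction evidence maps uniquely and
the truth table is exact. `simulate_reads()` draws 51-nt single-end reads
(the nominal trimmed read length of the study design; mates of a pair are
treated as independent reads throughout the package, since a 51-nt mate
either spans a junction or does not) with equal per-locus abundance.
Circular loci emit junction-spanning reads — the transcript rotation
`tail ∥ head` with both arms ≥ 20 nt — with probability
`junction_read_fraction` (default 0.5, balancing junction evidence against
body coverage), and the KO sample multiplies circular-locus junction-read
abundance by `ko_circ_ratio` (default 0.01) while all other abundances are
unchanged. Per-base substitution errors are available (`error_rate`,
default 0 so the planted truth is an exact oracle); a small-error mode
exists only to measure sensitivity loss.

The simulator does **not** model base-quality profiles, ligation or
structure-dependent coverage bias, paired-end fragment geometry, or
expression heterogeneity between loci. Passing the planted-truth tests
therefore demonstrates the correctness of the detection, aggregation,
comparison and annotation logic under clean conditions — not robustness to
the full noise structure of real libraries, where quality trimming,
mismatch tolerance (deliberately absent here) and abundance skew matter.

All randomness flows from the configured seed; read-generation seeds are
derived per sample so WT and KO are independent but reproducible.

## Problem sizes and determinism

The default simulated study — 100 kb genome, 20 circles among 61 loci,
200,000 reads per sample — runs end to end (both samples, detection through
depletion calls) in a few minutes on one core and recovers 20/20 planted
circles at exact coordinates with 20/20 called depleted and no linear
locus affected. The equivalence test against the brute-force split×scan
enumerator uses 1000 randomized genome/read cases (genomes up to 20 kb,
reads up to 60 nt, junction, linear, random, short and minus-strand read
types). Unit tests use smaller genomes (12–30 kb) and read counts
(hundreds to tens of thousands) chosen so each property is exercised with
comfortable margins.

## Known limitations

* Exact matching loses every junction read with a sequencing error in
  either arm; recall on real error-bearing libraries will be lower than on
  the error-free simulation, and the count filters are what absorb this.
* The depletion rule is a fixed-ratio threshold with no statistical model;
  with one biological replicate per condition there is nothing to
  estimate a variance from, and the published catalog shows the two
  classes are separated by an order of magnitude.
* The stem score is gapless and integer-valued; bulged stems score low
  even when a folding engine might pair them.
* The positional thirds rule for C/C′/D/D′ assignment is a formalization
  choice; borderline box placements near the third boundaries can flip
  the assignment (not the `is_cdbox` call itself unless the box is far
  from its terminus).

## A worked micro-example

```{r example}
cfg <- analysis_config()
sc <- sim_config(genome_len = 20000, n_circ_loci = 4, n_noncirc_cd_loci = 2,
                 n_linear_genes = 6, n_reads_per_sample = 4000, seed = 11)
sim <- simulate_genome(sc)
idx <- genome_index(sim$genome)
ann <- with(sim$truth, data.frame(name = locus_name, chrom = chrom,
                                  start = start, end = end))
wt <- simulate_reads(sim$genome, sim$truth, sc, "WT")
ko <- simulate_reads(sim$genome, sim$truth, sc, "KO")
cands_wt <- aggregate_sample(detect_sample(wt$reads, idx, cfg)$hits,
                             cfg, "small", annotation = ann)
cands_ko <- aggregate_sample(detect_sample(ko$reads, idx, cfg)$hits,
                             cfg, "small", annotation = ann)
compare_samples(cands_wt, cands_ko, cfg)
```

```{r catalog}
# the packaged catalog reproduces the published depletion split
cat31 <- tk_circ_catalog()
dep <- classify_depletion(cat31$circ_wt, cat31$circ_ko, cfg)
table(dep$call)
sum(dep$call == "depleted" & startsWith(cat31$locus, "sR"))
```
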