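---
title: "Detecting A-to-I RNA hyper-editing: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting A-to-I RNA hyper-editing: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette describes the statistical and algorithmic model behind
`hyperedit`: what the method assumes, how each parameter default was
chosen, what the synthetic-data generator does and does not emulate, the
numerical conventions used throughout, and the known limitations. Code
chunks illustrate the interfaces; they are not evaluated when the vignette
is built.

## 1. The detection model

### Why heavily edited reads go missing

ADAR deaminates adenosine to inosine in double-stranded RNA, and inosine
base-pairs like guanosine, so reverse transcription and sequencing report
each edited adenosine as an A→G mismatch against the genome. ADAR is
processive on long duplexes: once engaged, it can edit a large fraction of
the adenosines in a region, producing reads with many mismatches. A
standard aligner with a mismatch budget of a few percent of read length
rejects exactly those reads, so a pipeline that counts mismatches only in
*aligned* reads is blind to the most heavily edited molecules.

### The transformed-alphabet rescue

`hyperedit` recovers those reads with a four-stage scheme:

1. **Initial alignment.** All reads are aligned natively with a strict
   mismatch budget (`max_mm` per read, default 3 for the pipeline's
   initial pass). Reads with no unique placement within budget are set
   aside as *unmapped*.
2. **Alphabet transformation.** For a candidate mismatch type X→Y (e.g.
   A→G), every X is rewritten as Y in both the unmapped reads and the
   genome (`transform_scheme("A", "G")`). In this collapsed three-letter
   alphabet an X→Y mismatch is definitionally impossible, so a read whose
   only defect was dense X→Y editing aligns with few or no mismatches.
   Reverse-strand placements are handled by additionally transforming the
   reverse complement (for A→G this means T→C on the read).
3. **Transformed realignment.** Unmapped reads are realigned in the
   transformed alphabet, keeping only placements that are unique at the
   best mismatch count (`align_read()`; see §2).
4. **Native recovery and cluster calling.** At each accepted placement the
   original read is compared base-by-base with the original genome.
   Mismatches of the candidate type are the putative editing events; all
   other mismatches count against the read. A read is called
   *hyper-edited* when its candidate events reach a density threshold and
   pass the clean-read filters (§1.2).

### 1.1 The density threshold: `min_sites()`

A read of length $L$ must carry at least

$$\texttt{min\_sites}(L) = \lceil 0.05\,L \rceil$$

candidate events — 5% of its length, rounded up — so 4 events for an
80-bp read and 5 for a 100-bp read. Five percent was chosen to sit above
any plausible pile-up of sequencing errors plus SNPs on a single read
(error rates are ~0.1–1% per base and SNP density far lower), while
staying far below the edited fraction of a genuine ADAR target, where a
third or more of adenosines (roughly 8–10% of all bases) can be
converted. `detect_opts(strict = TRUE)` raises the rule to
$\lfloor 0.05 L \rfloor + 1$ (strictly *more* than 5%: 5 for 80 bp, 6 for
100 bp) for applications that prefer specificity over sensitivity.

Because ADAR requires a duplex, calling a read at $k$ sites implies a
lower bound on the edited fraction of the underlying double-stranded
region: both strands are substrates, so an $L$-bp duplex tagged by a
$k$-site read carries at least $k$ edits per strand, touching at least
$2k/L$ of its base pairs — **10% for an 80-bp duplex at the default
threshold**. `min_edited_fraction(80, min_sites(80))` returns exactly
0.10; this is the analytic quantity reported by `scripts/acceptance.R`.

### 1.2 Clean-read filters

Each candidate read must additionally satisfy (`detect_opts()` defaults in
parentheses):

* **Other-mismatch cap** (`max_other_frac = 0.025`): mismatches *not* of
  the candidate type may not exceed 2.5% of read length (2 for 80 bp). A
  read full of heterogeneous mismatches is a mapping artefact or a
  low-quality read, not editing.
* **Edge confinement** (`end_decile = 0.1`): if every candidate event
  falls within the first or last 10% of the read, the read is rejected.
  Genuine processive editing spreads across the read; events confined to
  one end are the signature of an adapter remnant or a splice-junction
  overhang.
* **Base quality** (`min_qual = 25`): the mean Phred quality at candidate
  positions must not be materially below the read's overall mean quality.
  Errors cluster at low-quality cycles; edits do not.
* **Optional trimming** (`trim_to = NULL`): reads may be truncated to a
  fixed length before detection so that datasets with different read
  lengths are screened under identical thresholds.

### 1.3 The twelve-type screen as a built-in control

`run_all_types()` runs the identical transform–realign–call procedure for
all 12 ordered mismatch types. Under the A-to-I hypothesis only A>G (and,
in unstranded libraries, its antisense image T>C) should yield clusters;
every other type measures the pipeline's false-positive behaviour under
exactly the same alignment and filtering conditions. Two summaries are
derived:

* `specificity()` — the fraction of A-to-G-family signal among all types,
  with G>A (+C>T when unstranded) singled out as the mirror-image
  yardstick: it involves the same two bases, so sequence-composition
  artefacts would inflate it symmetrically.
* `type_screen_null_check()` — a chi-squared test of uniformity across
  the non-candidate types; a skew flags a systematic artefact (e.g. a
  bisulfite-like chemistry problem inflating C>T).

In unstranded libraries the transcript strand is unknown, so A>G and T>C
calls are pooled into one A-to-G family and `collapse_sites()` projects
T>C reads onto the minus strand (a T>C site at genome position $p$
becomes an A>G site at $p$ on "−"). When `stranded = TRUE` the read's
alignment strand resolves the transcript strand directly and the pooling
is skipped.

### 1.4 Normalization

Datasets differ in depth, so raw event counts are not comparable.
`normalized_signal()` reports **editing events per million mapped bases**,
where mapped bases include both the initial pass and the rescued reads —
rescued reads are real transcriptome sampling and excluding them would
overstate the signal of heavily edited datasets. This is the quantity used
by `compare_datasets()` and `aggregate_replicates()` (mean ± standard
error across replicates).

## 2. The aligner

The transformed-space aligner is a gapless seed-and-extend index:

* k-mer index with `k = 16`; a read is scanned with
  `max_mm + 1` non-overlapping tiles. By the pigeonhole principle, a
  placement with at most `max_mm` mismatches must contain at least one
  exact tile, so the search is **exhaustive** whenever
  $L \ge (\texttt{max\_mm} + 1)\,k$ (64 bp at the defaults). Shorter
  reads fall back to fewer tiles and lose the guarantee.
* The per-read budget scales with length:
  `max_mm_scaled(L) = max(1, floor(0.04 L))` — 4% mirrors common
  short-read aligner defaults and, combined with the 5% calling rule,
  guarantees that a read dense enough to call could not have survived the
  initial native pass.
* Only placements that are **unique at the best mismatch count** are
  accepted; ties are discarded. Hyper-editing inference from an
  ambiguous placement (typically a repeat copy) would assign events to
  the wrong locus, which is worse than dropping the read.

The test suite checks the aligner against
`Biostrings::neditStartingAt` as an exhaustive oracle over every
placement on both strands.

## 3. dsRNA structure

ADAR substrates are duplexes, usually formed by inverted repeat copies in
the same transcript. Three complementary analyses:

* `find_dsrna_partner()` — Smith–Waterman alignment of the editing
  cluster against the **reverse complement** of its ±`flank` (default
  2000 bp) neighbourhood; a hit with identity ≥ 0.65 and query coverage
  ≥ 0.80 is a plausible pairing partner. 2 kb covers typical
  intra-transcript fold-back distances while keeping the search local;
  0.65/0.80 admit the diverged repeat copies that still pair thermodynamically
  while excluding chance similarity. A cluster inside a palindrome
  legitimately partners with itself.
* `control_same_strand()` — the same search against the *forward* strand
  of the flank with the cluster's own location masked. Same-strand hits
  cannot form a duplex, so the control rate estimates how often the
  detector fires on mere repetitiveness; a real editing set should show
  reverse-orientation hits well in excess of this control.
* `genomic_dsrna_potential()` — the genome-wide base rate: random 50-bp
  windows tested for a *strict* partner (identity > 0.95, length ≥ 40 bp,
  `word_size = 13`). The strict regime asks whether near-perfect
  fold-backs are ubiquitous in the genome (as in repeat-rich genomes)
  or rare, which calibrates how surprising the per-cluster hit rate is.

The Smith–Waterman core uses `match = 2, mismatch = −3, gap_open = 5,
gap_extend = 2` — the classic BLASTN-style regime that tolerates the
~10% divergence of repeat copies while penalizing gaps enough to keep
duplex alignments contiguous. `word_size = 7` is a seeding prefilter
(a shared 7-mer is required before running the full dynamic program);
`word_size = 1` disables the gate, and in that mode `local_align()` is
verified score-identical to `Biostrings::pairwiseAlignment` in the test
suite.

`dsrna_editing_enrichment()` then asks whether editing-site density
inside the union of each cluster and its predicted partner exceeds the
density elsewhere — under the duplex model, the partner region is itself
a substrate.

## 4. Motif profiles

ADAR has neighbour preferences: the base immediately 5′ of the edited
adenosine is depleted of G, and the 3′ neighbour shows species- and
isoform-dependent preferences. `build_profile()` tallies the −1 and +1
bases around each site and reports **enrichment** — site-adjacent base
frequency divided by background frequency — where the background is, by
default, all adenosines within the detected cluster spans
(`background = "cluster"`). Using the cluster-local background rather
than the whole genome cancels the composition bias of the repeat
elements that host most editing; `background = "genome"` is available
for comparison. Profiles from fewer than `min_confident = 50` sites are
flagged low-confidence rather than rejected.

`cluster_profiles()` groups datasets (e.g. species) by their preference
vectors using average-linkage hierarchical clustering on Euclidean
distances of **log2 enrichments**. The log scale is the principled choice
for multiplicative quantities: a two-fold depletion (0.5) is as far from
neutral (1.0) as a two-fold enrichment (2.0), whereas on the raw ratio
scale enrichments are unbounded and dominate depletions, letting a single
correlated dimension mask a real grouping.

## 5. Annotation

`overlap_fraction()` intersects sites with repeat/coding intervals
(0-based half-open BED semantics throughout). `unedited_expression()`
revisits the *initially mapped* reads at each hyper-edited locus: reads
covering known sites without carrying edits demonstrate that the locus
also produces unedited transcripts; per-site editing levels (edited /
covering reads) and a per-locus `edited_only` flag are reported. Sites
are tiered by level for plotting (`site_tier`: ≤1% weak, ≤30%
intermediate, else strong).

## 6. The synthetic-data generator

`sim_config()` + `build_genome()` + `simulate_reads()` produce a genome
and reads with complete ground truth, designed so every pipeline claim is
checkable exactly. What it emulates:

* **Genome**: i.i.d. background sequence at `gc_content = 0.42`
  (vertebrate-like), seeded with repeat families — by default 10 copies
  of a 300-bp consensus at 10% divergence, 80% of them placed as
  inverted pairs with a short spacer, plus 4 copies of a 200-bp
  palindromic consensus (`default_repeat_families()`). These are the
  dsRNA-forming substrates.
* **Transcripts**: tiled intervals of 1–3 kb on alternating strands,
  20% flagged coding.
* **Editing**: confined to dsRNA-capable spans (inverted-pair copies and
  palindromes) of transcripts, applied per *molecule* — a transcript
  copy is edited with probability `p_transcript_edited = 0.5`, and within
  an edited molecule each transcript-strand adenosine converts with
  probability `edit_rate_per_A = 0.3` (ADAR converts a substantial
  minority of adenosines in an engaged duplex), modulated by neighbour
  context: the preferred +1 base gets weight ×`motif_strength` (1.6),
  other +1 bases ×0.8, and an upstream G multiplies the rate by
  `upstream_G_depletion = 0.3`. On a minus-strand transcript the edit
  appears in genome coordinates as T→C, exactly as in real unstranded
  data.
* **Noise**: uniform sequencing errors (`seq_error_rate = 0.001` per
  base) and genomic SNPs (`snp_rate = 5e-4`), both recorded in the truth
  tables so tests can distinguish them from edits.
* **Controls**: `adar_null_control()` produces the same genome and read
  sampling with editing disabled — the negative control for the
  twelve-type screen.

Determinism: all generation runs under `withr::local_seed`, so the global
RNG state of the caller is never disturbed, and identical configurations
give byte-identical pipeline outputs (verified by checksum in the test
suite). `build_genome()` uses `seed`; `simulate_reads()` uses `seed + 1`
so genome and reads can be varied independently.

What the generator deliberately does **not** emulate: splicing and
junction-spanning reads, paired-end protocols, indels and structural
variation, position-dependent error profiles, expression-level
heterogeneity beyond uniform transcript sampling, and secondary-structure
thermodynamics (duplex capability is declared by construction, not
folded).

## 7. Numerical conventions

* All 5%-/4%-of-length thresholds are computed on exact rationals guarded
  with a ±1e-9 epsilon before `ceiling`/`floor`, so
  `min_sites(100)` is 5, not 6, despite `0.05 * 100` not being exactly
  representable in binary floating point.
* Genomic coordinates are 0-based half-open everywhere (BED convention);
  SAM output converts to 1-based on write.
* Motif distances use log2 enrichments (§4); enrichment values of 0 or
  non-finite values are mapped to neutral before the log.
* Chi-squared uniformity tests report exact `stats::chisq.test` p-values;
  expected counts below 5 produce a note rather than a hard failure.

## 8. Limitations

* The rescue aligner is gapless; an edited read that also spans an indel
  or splice junction is lost. The exhaustiveness guarantee requires
  reads of at least `(max_mm + 1) * k` bp (64 bp at defaults).
* Unique-placement filtering discards reads whose best placement is tied,
  which under-counts editing in recently duplicated, near-identical
  repeats — precisely where editing is common. Counts should be read as
  lower bounds there.
* In unstranded libraries the A>G/T>C pooling cannot resolve the edited
  strand when both strands are transcribed at a locus;
  `strand_resolved = FALSE` marks such sites.
* The per-million-mapped-bases normalization assumes comparable
  transcriptome composition across the datasets being compared; strong
  differential expression of edited loci will move the signal for
  non-editing reasons.
* `genomic_dsrna_potential()` is a sampling estimate; its precision is
  limited by `n_windows`, and it treats sequence identity as a proxy for
  pairing without computing folding energies.

## 9. A minimal session

```{r example}
library(hyperedit)

cfg <- pipeline_config(
  out_dir = tempfile("hyperedit-run-"),
  sim = sim_config(genome_length = 30000, n_reads = 5000, seed = 42)
)
run <- run_pipeline(cfg)

glance(run)            # one-row summary
run$screen$report      # the twelve-type screen
run$profile            # neighbour-preference enrichments
autoplot(run$profile)  # enrichment heatmap
```

See the README for a fully worked example with printed output.
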