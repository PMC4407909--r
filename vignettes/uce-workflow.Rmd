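---
title: "Methods: the ucetools UCE workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the ucetools UCE workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ucetools)
```

# The problem

Ultraconserved elements (UCEs) are short genomic regions with perfect
sequence identity between distantly related species. Because they are easy
to find in pairwise whole-genome alignments and easy to enrich by
hybridization capture, they make practical anchors for phylogenomic marker
sets in groups where transcriptomes or whole genomes are unavailable.
`ucetools` implements the complete in-silico side of such a workflow:
identifying UCEs, designing capture baits, recognising enriched loci in
assemblies, assembling supermatrices, and quantifying enrichment and
capture success.

This vignette records the models and the decisions behind each stage —
particularly the places where the design was genuinely open and a choice
had to be made.

# Conserved-region detection

A MAF alignment block is scanned column by column. A column continues a
conserved run only when every row carries the same unambiguous nucleotide;
comparison is case-insensitive (soft-mask case carries no evidence about
identity), while gap columns and `N` columns always break a run — perfect
conservation cannot be asserted through an indel or an unknown base.

Runs must be *strictly longer* than `min_len` (default 40 bp), matching
the "longer than 40 bp" convention of classic UCE screens. The threshold
is a parameter everywhere (function argument and CLI flag) because the two
customary operating points — a 40-bp floor at the scanning stage and
effectively 60-bp loci after screening — should both be reachable without
code changes.

Coordinates are reported 0-based half-open on the first row's source, in +
strand space (minus-strand rows are converted by
`start' = src_size − start − size`, and residues reverse-complemented), so
every downstream file speaks one coordinate language; 1-based inclusive
ranges appear only in charset/partition output, where phylogenetics
convention demands them. Regions are never merged across blocks, and
regions with identical coordinates from different blocks collapse to one.
Regions more than 25% lowercase are *flagged*, not discarded: the repeat
filter belongs to the bait stage.

# The local-similarity engine

Duplicate screening and contig matching both reduce to a decision of the
form "is this pair more than X% identical over more than Y% of a length
basis?". The engine behind both is an exact Smith–Waterman local alignment
(match +1, mismatch −1, linear gap −2) implemented in C++, searched on
both strands, with

* identity = matching columns / aligned columns, and
* coverage = aligned span on the basis sequence / that sequence's length.

At the scale this toolkit targets (hundreds of regions of ≤ ~1 kb) the
exact DP is fast enough that no heuristic seeding is needed for
region-vs-region work; a shared 14-mer prefilter is used in contig
matching purely to skip hopeless pairs, and an exact-seed + windowed
alignment search is used when locating baits on whole genome sequences.
Ties in the DP are broken deterministically (diagonal > up > left, first
best cell), so results are reproducible.

Open choices, and what was chosen:

* **Coverage basis.** For the duplicate screen, the shorter member of the
  pair — "a fraction of *their* length" is ambiguous, and the shorter
  basis is the conservative reading (more pairs qualify as duplicates).
  For bait/contig matching, the bait: contigs legitimately extend far
  beyond a 120-nt probe, so contig-based coverage would be meaningless.
  Both are arguments (`coverage_basis`).
* **Both members removed.** A duplicate-like pair removes *both* regions.
  If two loci cannot be told apart at 80% identity, a probe for either
  could pull in the other's paralog; neither is safe.
* **Strictness.** The duplicate screens use strict `>` (per "more than"),
  contig matching uses `≥`. Both appear explicitly in the function
  contracts.
* **Strand.** Reverse-complement matches count everywhere; paralogy is
  strand-agnostic.

# Bait design

Loci shorter than 180 bp are buffered to 180 bp with equal 5′ and 3′
flank; an odd remainder's extra base goes 3′ (an arbitrary but fixed
tie-break), and padding that runs off a sequence end shifts its deficit to
the other side, flagging the locus if the sequence itself is too short.
120-nt baits are tiled every 60 bp (2X density). When a locus length is
not a multiple of the stride, one extra bait is placed flush with the 3′
end so the locus is always fully covered — the closed form
`(L − 120)/60 + 1` holds exactly for tileable lengths and is verified for
every L in {120, ..., 1020} in the tests.

Bait filters are strict inequalities: any ambiguous base call fails;
soft-masked (lowercase) fraction must not exceed 0.25; GC fraction
(case-insensitive) must not exceed 0.70. A bait at exactly 25% repeat or
70% GC therefore passes. Repeat content is measured as the lowercase
fraction because the design genome arrives repeat-masked; no masker is
bundled.

Deduplication collapses byte-identical baits (keeping the lowest locus
number, then the lowest bait index) and removes both members of
cross-locus near-duplicate pairs at the same thresholds as the locus
screen (>80% identity over >50% of the shorter bait) — the locus-screen
thresholds are the natural default and are configurable. Pairs from the
same locus are exempt: 2X tiling *guarantees* neighbours share exactly
half their length, and the 60/120 = 0.50 overlap also sits exactly at the
non-strict boundary.

# Harvesting loci from assemblies and genomes

Every bait is aligned to every contig of a taxon (both strands); hits need
80% identity over 80% of the bait. Multiple baits of one locus hitting one
contig are the norm under 2X tiling and count as a single locus-level
match (best identity kept). Two screens then protect orthology, in this
order:

1. a contig hit by baits of two or more distinct loci is removed entirely
   (`multi-locus`), before any further counting — a chimeric or
   misassembled contig should not also poison the loci it touches;
2. a locus hit by two or more *surviving* contigs in one taxon is marked
   absent for that taxon (`duplicate-contig`).

Equal evidence for two locus assignments is treated as multi-locus
(removal), the conservative resolution. Survivors populate a two-table
relational store — locus × taxon detection status plus a contig-name map —
written as plain CSV so it is diffable and portable. When harvesting from
a genome rather than an assembly, bait hits of a locus are merged into
genomic sites, a locus matching two or more sites is dropped (first-pass
duplicate removal; best-hit resolution would be the alternative, and the
drop is the conservative default), and each surviving site is emitted with
1000 bp of flank, clamped at sequence ends and reverse-complemented into
bait orientation for minus-strand sites.

# Matrices and statistics

A locus enters an *f*-complete matrix when it has data for at least
`ceiling(f · N)` of the N taxa under study; the ceiling reproduces both
customary worked values (70% of 14 → 10; 75% of 44 → 33). A column is
parsimony-informative when at least two unambiguous states each occur in
at least two taxa; gaps, `?` and IUPAC ambiguity codes are missing data,
never states. Concatenation orders loci lexicographically by id, fills
absent taxa with `?` (distinct from the alignment gap `-`), and records
1-based inclusive charsets. Summary tables report a 95% CI as the
half-width `1.96 · sd / √n` (sample SD; reported as 0 with a flag for a
single alignment); whether such intervals are half-widths or full widths
is a perennial ambiguity, so the definition is fixed here and in the
documentation.

The bundled `edge_trim()` is a deliberately simple fallback: columns are
cut from each end until a 20-column window reaches mean pairwise identity
0.5 *and* the boundary column itself qualifies (so leading all-gap
columns can never survive inside a half-qualifying window). It never
touches interior columns and is **not** equivalent to dedicated trimming
tools; pre-trimmed alignments are accepted everywhere.

qPCR fold enrichment is `efficiency^|ΔCp|` with ΔCp the difference of
replicate-mean crossing points and a default efficiency of 1.78 per
cycle. Pool summaries average *fold values* (matching the "average fold
enrichment" convention); averaging on the ΔCp scale first is available as
an option since the two differ for heterogeneous pools.

Capture-success models are ordinary `stats::glm()` fits — Poisson with log
link for locus counts, Gaussian with identity link for mean locus lengths
— over per-taxon covariates (genetic distance to the design genome on
[0, 1], read counts, mean read length, assembly method). The toolkit's own
contribution is the ranking arithmetic: `AIC = 2k − 2lnL`, Akaike weights
`w_i = exp(−Δ_i/2)/Σ exp(−Δ_j/2)`, and model averaging over the candidate
set with `w_i > 0.10` after renormalization. Averaging is
*zero-substitution* by default (a term absent from a model contributes 0),
with conditional (per-term renormalized) averaging switchable — the two
conventions answer slightly different questions and neither is universal.
Pairwise genetic distance is consumed as an input column; estimating it is
out of scope.

# The synthetic-data generator

All tests and the acceptance script run on generated data with planted
truth. The generator emulates:

* a pair of genomes (default 60 kb) sharing planted, perfectly conserved
  elements (default 50, 60–200 bp, ≥ 500 bp apart) on a background
  mutated independently in each genome at a 15% substitution rate;
* near-identical duplicated copies (default identity 0.90) planted as
  additional intervals, so a screen removing both members of each pair is
  checkable by count;
* soft-masked repeat tracts, and optionally fully masked elements, to
  exercise the bait repeat filter;
* per-taxon contigs (locus ± ≤ 400 bp flank) diverged at a chosen
  substitution rate, with optional chimeras, extra copies, decoys and
  alternating reverse-complementation;
* Cp tables with known ΔCp and optional replicate noise.

Everything is a pure function of (spec, seed): identical inputs give
byte-identical files. One construction detail matters for exact
coordinate recovery: when the background rate is positive, the single
background base flanking each element is forced to differ between the two
genomes. Without this, a flanking column matches by chance with
probability ≈ 0.75 at the default divergence and planted elements would
not be *maximal* conserved runs; with a zero background rate nothing is
forced and the genomes are identical by design. The truth MAF contains
one gapless block per planted interval (element ± 50 bp of background), so
no external aligner is needed.

What the generator does **not** emulate — and hence what passing tests do
not demonstrate about real data: indel evolution inside or around
elements, rearrangements, alignment error from a real whole-genome
aligner, GC or repeat landscape heterogeneity, sequencing error and
coverage variation, or contamination across taxa. The generator validates
the *logic* of the pipeline against planted truth, not the behaviour of
upstream aligners and assemblers.

# Numerical and scale choices

* Alignment scoring is fixed at match +1, mismatch −1, linear gap −2; the
  contracts are threshold *decisions*, which the tests check against an
  independent Smith–Waterman implementation on hundreds of random pairs.
* Problem sizes in the tests and the acceptance script — 50-element
  genomes of 60 kb, 40-locus harvests at 5% divergence, 500-case oracle
  sweeps, n = 200 GLM recovery — were chosen as the smallest sizes at
  which each property is sharply testable (exact counts, coordinate
  identity, 3-SE parameter recovery) while a full run stays in the tens
  of seconds on one core.
* Degenerate inputs are contracts, not surprises: single-row MAF blocks
  and empty region sets error or warn explicitly; a genome shorter than
  the buffer target yields a *flagged* locus; loci shorter than one bait
  tile to an empty set and are reported as dropped.

# Known limitations

* The conserved-region scan operates within alignment blocks and never
  merges adjacent regions across block boundaries; a fragmented upstream
  alignment fragments loci accordingly.
* The harvest identity screen is statistical at its margins: a true
  ortholog diverged well beyond the nominal threshold can occasionally
  present a local alignment above 80% identity over 80% of a bait. The
  thresholds bracket recovery (complete at 5% divergence, collapsing at
  25%) but are not a step function.
* Multiple-sequence alignment, alignment trimming beyond the fallback
  above, tree inference, read processing and distance estimation are
  upstream/downstream of this package by design; it consumes and produces
  their standard formats instead.
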