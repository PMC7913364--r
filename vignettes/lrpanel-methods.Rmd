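---
title: "Methods behind lrpanel: panel accounting, pooling stoichiometry, read-backed phasing, and breakpoint resolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind lrpanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrpanel)
library(tibble)
```

`lrpanel` supports a diagnostic workflow in which entire disease loci are
tiled with long-range (LR) PCR amplicons of roughly 4–20 kb, pooled,
sheared, and sequenced as a short-read paired-end library. This vignette
explains the models and procedures in the package, the parameters that
matter, the numerical choices, and what the simulation-based tests do and
do not demonstrate.

## Coordinates and the panel model

All internal coordinates are 1-based and inclusive, the HGVS `g.`
convention in which locus spans and breakpoints are published; the length
of an interval is `end - start + 1`. BED-derived panel files are 0-based
half-open and are converted at the file boundary only
(`read_panel()`/`write_panel()` round-trip exactly). We chose the HGVS
convention internally because every quantity the package reports —
deletion lengths, microhomology intervals, ambiguous breakpoint forms — is
exchanged in that convention, and a single conversion site at I/O is far
less error-prone than converting at each computation.

A panel is a tibble of amplicons grouped into loci. Three structural rules
are enforced at load: amplicons of one locus share a contig; primer sites,
when given, sit at and within the two amplicon ends; and loci never overlap
one another (each base of the genomic target is attributed to exactly one
locus, so per-locus sizes sum to the panel total). The per-locus genomic
target is the size of the union of amplicon intervals — adjacent amplicons
of multi-PCR loci deliberately overlap, and those stretches count once.
Union, gap, and overlap queries are delegated to IRanges; the package's
property tests verify them against a naive per-base occupancy scan on
randomized loci, and check order-invariance and the identity
`target size = union + gaps` within a declared target.

Strand is deliberately ignored in panel accounting: amplicon spans are
symmetric in strand, and primer orientation is carried only as the
forward/reverse site metadata used by the allele-dropout check.

### Allele dropout

A PCR cannot amplify an allele whose primer-binding site is deleted; the
locus then looks homozygous for the remaining allele with no other trace
of the CNV. `ado_risk()` intersects a candidate deletion with every
amplicon and classifies it: primer site hit (ADO risk), amplicon fully
contained (no product at all from that allele), or strictly internal
(breakpoints sequenceable — the favourable case). When a panel file lacks
primer columns the amplicon's terminal 30 bp stand in for the primer
sites, with a warning; 30 bp brackets the typical LR primer length
(26–30 nt) and errs on the side of flagging. The complementary signal —
a region whose variant calls are exclusively homozygous — is surfaced by
`homozygosity_warning()`, with a default of at least 5 calls before the
pattern is reportable: below that, all-homozygous stretches are common by
chance and the warning would be noise.

## Pooling stoichiometry

The calculators are deterministic algebra, kept separate so each step of
the protocol can be recomputed and audited:

* **Dilution**: C1·V1 = C2·V2, refusing "upward" dilution. Unit-agnostic.
* **Amplicon pooling**: after dilution to a common mass concentration
  (10 ng/µL in the protocol), volumes proportional to amplicon size make
  the pool equimolar per amplicon copy: mass_i ∝ size_i implies
  moles_i = mass_i/(660·size_i) is constant, so every base position of
  the panel is represented equally in the sheared library. The pool must
  reach a minimum total volume (default 130 µL, the shearing input).
* **Molarity**: nM = c[ng/µL]·10⁶/(660·L[bp]), the standard 660 g/mol/bp
  average mass of a double-stranded base pair. Libraries are normalised to
  4 nM before index pooling.
* **Index pooling**: libraries at a common molarity are combined with
  volumes proportional to their genomic target sizes, equalising expected
  per-base depth across samples sequenced together.
* **Spike-in**: a targeted library added to an exome pool in the ratio
  `lr_target / wes_target` of the two target sizes. The operation is a
  pure ratio and unit-agnostic, because spike-in amounts are quoted
  variously in attomoles, nanograms, or library fractions.

Volumes are rounded to 0.1 µL — a pipettable resolution — with the
rounding residue pushed onto the largest component so totals remain exact;
`round_to = NULL` disables rounding. A per-amplicon floor (default 1 µL)
may force a proportionally larger pool; the plan records when that
happened. Properties tested: mole conservation across dilutions, scale
invariance of size-proportional pooling, exact totals after rounding, and
the molarity→4 nM dilution round trip.

## Read-backed phasing

Two candidate variants of a recessive gene explain disease only in trans
(compound heterozygosity). When relatives are unavailable for segregation
analysis, the sequencing fragments themselves carry phase: a fragment
(read pair) that co-observes two heterozygous sites votes **cis** if it
shows the same allele class at both (ALT/ALT *or* REF/REF — between two
genuinely heterozygous sites, the reference-carrying molecule is exactly
the other haplotype, so REF/REF is equally valid cis evidence) and
**trans** otherwise. Distant candidates are connected through chains of
intervening informative heterozygous sites, and relative phase is the XOR
of parities along the chain.

`build_phase_graph()` tallies votes per site pair into edges carrying the
majority parity, a support count, and a conflict count.
`phase_pair()` then:

1. keeps only edges with `support >= min_support` (default 2 fragments)
   and conflict fraction `conflicts/(support+conflicts)` at most
   `max_conflict_fraction` (default 0.2);
2. labels the component of the start site by breadth-first parity
   propagation;
3. returns `unresolved` if the two sites are not connected, **or** if any
   edge inside their component contradicts the propagated labels — an odd
   cycle means two paths would disagree, and a diagnostic call must not be
   decided by majority vote;
4. otherwise reports cis/trans with the path, its weakest edge support,
   and the total conflicting fragments along it.

The defaults (base quality ≥ 20, mapping quality ≥ 20, support ≥ 2,
conflict fraction ≤ 0.2) are conservative automation choices for a
procedure usually performed by visual inspection, and all are exposed as
arguments and CLI flags. Mates contradicting each other at a site blank
that site for the fragment. Indel alleles are matched through alignment
operations at the site (a deletion or insertion of the right length and
content at the right position), assuming upstream left-alignment;
fragments observing fewer than two sites carry no phase information and
are dropped.

Correctness is checked against a brute-force minimum-error-correction
(MEC) oracle: enumerate all 2^(n−1) haplotype bipartitions of n sites,
score each by the minimum per-fragment mismatch count, and read the
relative phase of a site pair off the minimising set. On error-free random
instances (≤ 10 sites, ≤ 30 fragments) the graph call equals the MEC phase
whenever the MEC solution is unambiguous, and is `unresolved` exactly when
the MEC optimum is ambiguous. A separate stochastic test adds 1%
substitution error and verifies that conflict counting prevents confident
wrong calls. Chain length is unbounded by default: how many intervening
sites a real case needs depends on the density of informative
heterozygous variants, which the method cannot influence.

## Deletion breakpoints and microhomology

Sequencing an amplicon that spans a deletion junction gives an observed
sequence that differs from the reference by one contiguous deletion. With
P the longest common prefix and S the longest common suffix of reference
and observed sequence:

* deletion length = |ref| − |obs| (identical for every placement);
* placement slack = P + S − |obs| = microhomology length *mh*;
* the deletion start may be placed at any of the *mh* + 1 positions in
  `[|obs| − S + 1, P + 1]`, each paired with the corresponding end.

Microhomology defined as placement slack equals the length of the
identical sequence present at both flanks, and is computable from the two
sequences alone, without repeat annotation. `N` bases never extend a
match — under ambiguity the conservative choice is a shorter
microhomology and fewer claimed placements. If P + S < |obs| the sequences
differ by more than one clean deletion and the function refuses to call
rather than mis-report a complex event; producing the observed consensus
from raw reads is upstream's job (a naive majority-consensus helper over
aligned reads is included for simulator output).

Reporting follows HGVS `g.` nomenclature. With no microhomology the
placement is unique (`ctg:g.start_enddel`). With microhomology the default
is the explicit ambiguous form `ctg:g.(a_b)_(c_d)del` over the placement
intervals — when repetitive flanks make the breakpoint genuinely
ambiguous, the notation should say so — while the conventional 3′-shifted
exact form is available via `report_mode = "shifted"`. A parser
(`parse_hgvs_del()`) round-trips both forms, and
`deletion_vcf_record()` emits the equivalent symbolic `<DEL>` record with
CIPOS/CIEND-style ambiguity fields. Flanking repeats (e.g. an Alu pair)
are annotated by side with `annotate_flanking_repeats()`. Homopolymer-
aware placement (e.g. a breakpoint inside an A-rich run with mismatches)
is out of scope: the package reports the algebraic placement set and does
not guess beyond it.

The independent oracle here is exhaustive removal-and-compare: delete
every possible window of the right length from the reference and collect
the start positions that reproduce the observed sequence. Property tests
verify the placement set equals the oracle's on random planted deletions
(including accidental microhomology extensions), and that planted
deletions of 50–5,000 bp with 0–12 bp microhomology are recovered exactly
in every clean simulation.

## Coverage QC

`depth_profile()` counts aligned read bases per position (CIGAR-aware:
deletions in a read contribute nothing at deleted bases), matching the
semantics of the coverage plots used to inspect panel data. Duplicate
reads are kept: amplicon libraries are PCR-derived, so duplicates are
expected signal, and no deduplication step exists in the workflow.
`gap_report()` returns maximal intervals below a depth threshold (default
20×, a common minimum for confident diagnostic variant calling; exposed
as an argument). Depth sums are tested against per-read accumulation, and
gap/covered intervals partition the region independent of read order.

## The simulator and what the tests show

The generators produce every fixture the tests need, deterministically by
seed:

* `make_reference()`: uniform-random A/C/G/T sequence.
* `plant_deletion()`: rewrites the 3′ flank so its first *mh* bases repeat
  the deleted segment's first *mh* bases, then deletes. By default the
  bases bordering the planted repeat are adjusted so no accidental flank
  identity extends the microhomology, making the truth placement set
  exactly *mh* + 1 positions; `exact = FALSE` leaves accidental
  extensions in place (useful for oracle-equivalence tests).
* `simulate_fragments()`: paired 151 bp reads from two haplotypes sampled
  equally, insert length Normal(375, 25) truncated to the read/haplotype
  range, per-base substitution errors, emitted as aligned records with
  CIGARs constructed from the haplotype's variant map — no external
  aligner is involved, and each fragment's source haplotype is recorded
  as truth. Read geometry defaults mirror a 2×151 bp run of a 350–400 bp
  insert library.
* `simulate_amplicon_pool()`: reads per amplicon independently, so
  overlap regions receive summed depth. `placement = "tiled"` lays
  deterministic non-overlapping tilings giving every amplicon base
  exactly `depth` aligned bases — the noiseless mode in which overlap
  depth is exactly 2× — while `placement = "random"` draws fragments
  uniformly and shows the read-length edge ramps of real data.

The error model is substitution-only; indel sequencing errors are not
simulated, so phasing and breakpoint truth stay unambiguous. The
simulator also does not model PCR chimeras, polymerase slippage, quality
degradation along reads, GC-dependent coverage, or real repeat structure.
Consequently, passing tests demonstrate the *algorithms* — parity
propagation, conflict handling, placement algebra, depth accounting — not
robustness to artefacts of real libraries; on real data the conservative
thresholds and the refusal to resolve conflicting evidence are the
intended safety margin.

Problem sizes used by the test suite and the acceptance script — a few
hundred to a thousand phasing instances of ≤ 10 sites and ≤ 30 fragments,
one to two hundred breakpoint sequences of ≤ 2 kb, one hundred planted
deletions up to 5 kb, simulated regions of a few kb at 20–100× — were
chosen as the smallest sizes at which the brute-force oracles are still
exhaustive and the stochastic properties are stable across seeds.

## Known limitations

* Phasing requires a chain of informative heterozygous sites bridgeable
  by ~350–400 bp fragments; sparse heterozygosity leaves pairs
  `unresolved` (correctly, but unhelpfully).
* Genotypes composed of two different ALT alleles (e.g. `1/2`) are not
  representable as REF/ALT fragment observations and are dropped.
* `infer_deletion()` handles exactly one contiguous deletion; junctions
  with inserted bases or nearby secondary variants raise an error instead
  of a call.
* Panel accounting treats loci as disjoint; designs with intentionally
  overlapping loci must be merged upstream.
* The 124-PCR, 35-locus size table bundled as an example carries only
  per-locus totals, not amplicon coordinates, so per-amplicon queries on
  it are synthetic single-interval stand-ins.
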