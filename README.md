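# lrpanel

Computational support for long-range (LR) PCR amplicon panel sequencing in
Mendelian diagnostics.

Capture-based assays (exomes, hybridisation panels) leave intronic and
repetitive stretches of disease loci uncovered, miss copy-number variant
(CNV) breakpoints, and cannot tell whether two candidate variants of a
recessive gene sit on the same chromosome copy. An alternative is to tile
entire loci with long-range PCR amplicons (4–20 kb), shear and pool them,
and sequence the pool as a short-read paired-end library. The wet-lab side
of that workflow leans on a surprising amount of arithmetic — target-size
accounting, dilution and pooling stoichiometry, molarity normalisation —
and the analysis side on a handful of small algorithms that are usually
done by eye: read-backed phasing and breakpoint/microhomology resolution.
`lrpanel` implements all of these as composable, data-frame-first R
functions, plus a seeded simulator so every computation can be exercised
without patient data.

## What it computes

**Panel accounting** (`read_panel()`, `locus_target_size()`,
`panel_target_size()`, `find_gaps()`, `overlap_regions()`, `ado_risk()`).
A panel is a tibble of amplicons grouped into loci. The genomic target of a
locus is the size of the union of its amplicon intervals (overlaps counted
once); gaps are the maximal uncovered intervals inside a locus target, and
a deletion that intersects a primer-binding site is flagged as an
allele-dropout (ADO) risk — the assay would amplify only the unaffected
allele and show a deceptively homozygous locus.

**Pooling stoichiometry** (`dilution_plan()`, `amplicon_pool_volumes()`,
`library_molarity()`, `index_pool_volumes()`, `spikein_amount()`).
Dilutions follow C1·V1 = C2·V2. Amplicons diluted to a common mass
concentration are pooled with volumes proportional to amplicon size, which
makes the pool equimolar per amplicon copy (mass_i ∝ size_i ⇒
moles_i constant). Library molarity uses the standard dsDNA conversion
nM = c[ng/µL]·10⁶ / (660 · L[bp]); indexed libraries at a common molarity
are pooled proportionally to genomic target size, and a targeted library is
spiked into an exome pool in the ratio of the two target sizes.

**Read-backed phasing** (`extract_informative_sites()`,
`collect_fragment_observations()`, `build_phase_graph()`, `phase_pair()`,
`phase_candidates()`). Each fragment (read pair) that co-observes two
heterozygous sites votes cis (same allele class at both) or trans
(opposite). Votes are tallied into a parity graph; the phase of two distant
candidates is the XOR of edge parities along a connecting chain of
informative heterozygous sites. Edges need a minimum fragment support, a
bounded conflict fraction, and parity-inconsistent components are reported
`unresolved` rather than majority-voted — a diagnostic must not overcall.
The brute-force minimum-error-correction bipartition is used as an
independent oracle in the test suite.

**Breakpoint resolution** (`infer_deletion()`, `deletion_length()`,
`microhomology_from_intervals()`, `format_hgvs()`,
`annotate_flanking_repeats()`). Comparing a junction-spanning sequence to
the reference, with P the longest common prefix and S the longest common
suffix, the deletion length is |ref| − |obs| and the placement slack
P + S − |obs| equals the microhomology length: mh + 1 equivalent
placements delete exactly the same number of bases. Calls render as exact
HGVS (`ctg:g.start_enddel`), 3′-shifted, or the explicit ambiguous form
`ctg:g.(a_b)_(c_d)del` when repetitive flanks genuinely preclude a unique
breakpoint.

**Coverage QC** (`depth_profile()`, `gap_report()`,
`homozygosity_warning()`) and a **seeded simulator** (`make_reference()`,
`plant_deletion()`, `simulate_fragments()`, `simulate_amplicon_pool()`)
that emits already-aligned read tibbles with ground-truth haplotype and
placement records.

Results are tibbles throughout; fitted objects carry `tidy()`/`glance()`
methods and `autoplot()` plots. A thin command-line wrapper
(`inst/cli/lrpanel`) exposes everything as `panel|pool|phase|breakpoint|
depth|sim` subcommands.

## Worked example

```r
library(lrpanel)

# 35-locus IRD panel accounting from the bundled per-locus size table
sizes <- readr::read_tsv(lr_example("ird_locus_sizes.tsv"), show_col_types = FALSE)
panel_stats(panel_from_locus_sizes(sizes))
#> # A tibble: 1 × 3
#>   n_loci n_amplicons total_target_bp
#>    <int>       <int>           <int>
#> 1     35          35         1814698

# deletion breakpoint with a 3 bp microhomology: 4 equivalent placements
infer_deletion("AAAACCTGGGGCCTTTTT", "AAAACCTTTTT", contig = "toy")
#> <lr_deletion_call> toy: 7 bp deleted, microhomology 3 bp ('CCT')
#>   toy:g.(5_8)_(11_14)del

# size-proportional pooling of three amplicons at 10 ng/uL
amplicon_pool_volumes(tibble::tibble(
  name = c("ABCA4_1", "ABCA4_2", "ABCA4_3"),
  size_bp = c(17600, 19900, 4300)))
#> <lr_pool_plan> 3 components, total 130.0 uL (volume proportional to amplicon size)
#>   name    size_bp volume_uL
#> 1 ABCA4_1   17600      54.7
#> 2 ABCA4_2   19900      61.9
#> 3 ABCA4_3    4300      13.4
```

The panel total of 1,814,698 bp (~1.81 Mb) is the genomic footprint a
sample sequenced over the full panel would cover. The deletion call shows
the two breakpoint ambiguity intervals: any start in 5..8 paired with the
corresponding end in 11..14 deletes the same 7 bases, because the 3 bp
sequence `CCT` is present at both flanks. The pool plan allocates the
130 µL shearing input so each amplicon contributes equal molar copies.

A phasing run on simulated data — two candidate indel variants 19 bp apart
on opposite haplotypes, 2×151 bp reads at 50× — resolves them as trans
(compound heterozygous) with 59 supporting fragments and no conflicts:

```r
phase_candidates(sim$alignments, variants, "ctg:1-1200", candidates = cands)
#>   call  path  min_support conflicts
#> 1 trans 1->2           59         0
```

(see `vignettes/lrpanel-methods.Rmd` for the full simulation setup).

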