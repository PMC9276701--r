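---
title: "Designing DdCBE and mDdCBE targets and quantifying their editing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing DdCBE and mDdCBE targets and quantifying their editing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddcbetools)
```

## The editors and the design problem

DddA-derived cytosine base editors (DdCBEs) deaminate cytosines in a 5'-TC
context within double-stranded DNA. The canonical editor is dimeric: the
deaminase is split into two inactive halves, each fused to a TALE
DNA-binding array, and catalysis is reconstituted only when the two TALEs
bind convergently on opposite strands with a short spacer between them.
Monomeric editors (mDdCBEs) instead fuse a non-toxic full-length deaminase
to a single TALE and edit downstream of its binding site. The dimeric
architecture imposes much stronger sequence requirements — two TALE sites
plus a constrained spacer — so a fraction of 5'-TC targets in a genome can
only be reached monomerically. Quantifying that fraction, designing
constructs for a chosen cytosine, and measuring realized editing (on-target
and genome-wide off-target) from deep sequencing are the three jobs of this
package.

All coordinates are 0-based, half-open, on the forward strand; strand-
specific sequences are derived views. Organellar genomes are treated as
circular by default, so motifs, sites and spacers may span the origin
junction; every scan is invariant under rotation of a circular genome and
under reverse complement, and the test suite checks both properties.

## The targetability scan

A TC motif is a 5'-TC dinucleotide on either strand; the C is the
deamination target. On the forward strand a bottom-strand motif appears as
GA, recorded at the G (the base complementary to the edited C).

A candidate TALE binding site is any interval of 14–20 bp whose bound-strand
sequence starts and ends with thymidine (the termini preferred by
golden-gate-assembled TALE arrays; the requirement can be relaxed with
`require_terminal_T = FALSE`). A dimeric design is a left site bound on the
forward strand and a right site bound on the reverse strand separated by a
14–18 bp spacer containing at least one TC motif. Exactly this one
orientation is enumerated: the mirrored assignment is the same physical
configuration read from the other strand. A monomeric design is a single
site together with the TC motifs lying within 18 bp downstream of its
3'-terminal thymidine, with offsets counted 1-based from that thymidine.

Two conventions are genuinely open in these criteria and are exposed as
parameters rather than hard-coded:

* **Spacer membership** (`spacer_motif_rule`). A motif straddling a spacer
  boundary can be counted if its C lies inside (`"c_only"`) or only if the
  whole TC dinucleotide lies inside (`"dinucleotide"`). The package defaults
  to the dinucleotide rule: on the packaged human mitochondrial reference it
  yields the reported monomeric-only fraction of 8.4% of all TC motifs,
  whereas the C-only rule yields 4.6%.
  Mechanistically the stricter rule corresponds to requiring the whole
  recognition dinucleotide to be exposed between the TALE footprints.
* **Window anchor** (`window_anchor`). "Within 18 bp" of the site's terminal
  thymidine can be measured to the motif's C (default) or its T. On the
  mitochondrial reference the two conventions select identical motif sets —
  the one-base shift washes out because sites are searched on both sides —
  so the choice is presentational; both are tabulated.

`editability_report()` classifies every motif (none / dimeric / monomeric /
both, deduplicated across placements: editability is set membership, not a
count of designs) and, by default, tabulates all eight convention
combinations (anchor × topology × spacer rule) so the sensitivity of the
headline fraction is always visible. On the packaged reference the fraction
moves from 8.37% (circular) to 8.70% (linear): the origin junction
contributes a handful of wrap-around designs.

The report is backed by a vectorized per-position engine (difference arrays
over site-existence flags) rather than by materializing every design; the
test suite proves the engine identical to the exhaustive enumerators, and
the enumerators identical to an independent brute-force oracle, on hundreds
of random genomes.

## Design ranking

`design_for_target()` validates that the requested position is a TC-context
cytosine (reporting the observed dinucleotide otherwise) and returns every
dimeric and monomeric design covering it. Monomeric editing concentrates at
offsets 4–11 downstream of the TALE site, so monomeric designs are ranked
by `1 / (1 + d)`, where `d` is the distance from the target's offset to
that preferred window (0 inside). Any monotone transform would order
designs identically; this one is bounded, and ties are broken by shorter
offset and then smaller site start. No intra-spacer position preference is
established for dimeric pairs, so they are listed unranked.

## Conversion calling and the off-target summary

`pileup_conversions()` computes per-position conversion evidence from
aligned reads (plain-text SAM or BAM; conversion, sorting and pileup run on
htslib via Rsamtools). For every reference C the conversion product is T;
for every reference G it is A — the same biological C-to-T event read from
the other strand, and the two are pooled downstream. Policy choices, all
surfaced as `caller_params()`:

* The rate denominator counts reads with a base call of any nucleotide
  passing the quality filters (Phred ≥ 20 base and mapping quality by
  default); mismatches to other bases stay in the denominator only.
  Deletions and N calls are excluded from depth.
* Positions with depth below `min_depth` (default 100) are flagged with an
  undefined rate rather than silently reported as zero.
* Overlapping mate pairs are not deduplicated internally; the packaged
  simulator emits single-end reads, and paired amplicon input should be
  overlap-clipped upstream if double-counting matters.

`summarize_offtarget()` applies the standard exclusion filters: positions inside any
on-target window are excluded, as are positions converting at ≥ 50%
(inclusive bound), which behave as pre-existing cell-line variants rather
than editing. The genome-wide average is the arithmetic mean over **all**
retained C/G positions, not only those above the 0.1% candidate threshold.
This distinction is load-bearing: an untreated control averages far below
0.1%, which would be arithmetically impossible if the mean were restricted
to positions passing the candidate filter. Candidates (≥ 0.1% after
exclusion) are listed separately. The summary refuses to report a mean when
no position survives the exclusions.

## Editing-window profiling

`align_profile_to_site()` converts per-position editing percentages into
strand-relative offsets from a site's 3'-terminal thymidine (flipping
orientation for reverse-strand sites and dropping offsets ≤ 0), the same
coordinate system the scan's `mono_window` uses. `aggregate_window()`
averages profiles per offset and calls the editing window as the longest
contiguous run of offsets whose mean reaches at least half the peak mean
(ties resolved toward the run containing the peak). The empirical window is
only loosely defined, so the relative-height rule and its threshold are
explicit, tunable, and echoed in the output. Degenerate inputs behave
predictably: a flat nonzero profile spans all observed offsets; an all-zero
profile yields an empty window. On nine synthetic profiles elevated exactly
at offsets 4–11 the caller returns [4, 11].

## The simulator: what it emulates and what it does not

`simulate_genome()` draws a background at a chosen GC fraction (default
0.44, matching the mitochondrial genome) and writes planting directives
over it: bare motifs, monomeric sites with a target at a chosen offset, or
dimeric pairs with a chosen spacer. Planted segments use G/C filler so they
never introduce unintended thymidine-ended sites of their own; the random
background may still contain designs, which round-trip tests tolerate by
asserting containment of the planted truth rather than uniqueness.

`simulate_reads()` emits pre-aligned, coordinate-sorted SAM (alignment is
out of scope; a FASTQ export exists for users who want to run a real
aligner). Reads tile the genome uniformly so depth is exact at every
position, substitutions are drawn independently per read at the programmed
fractions, and sequencing errors are applied afterwards at a uniform rate
to a random different base — so realized conversion fractions slightly
exceed programmed ones by about one third of the error rate at reference
C/G positions, and tests account for that. Base qualities are uniformly
high and coverage has no strand bias, quality decay, PCR duplicates or
structural variation; passing recovery tests therefore demonstrates the
correctness of the counting and filtering logic, not robustness to
real-library artifacts. Both simulators are fully determined by their
seeds, byte for byte.

## Numerical and scale choices

* The headline scan runs on the full 16,569 bp mitochondrial reference in
  well under a second; no approximation is involved anywhere in the scan —
  all counts are exact set cardinalities.
* Oracle-equivalence and symmetry properties are exercised on 200 random
  genomes of 40–100 bp (both topologies) plus all rotations of 20 circular
  genomes of 200–300 bp; these sizes give the brute-force oracle full
  coverage of junction-spanning cases while keeping the suite quick.
* Off-target recovery is validated at depth 1,000 over a 2 kb genome with
  50 background positions programmed at 0.3%, two homoplasmic SNVs and one
  20 bp on-target window at 20%; the recovered genome-wide mean is required
  to sit within three binomial standard errors of the programmed mean.
* The sub-threshold control property uses a 0.02% background at depth
  20,000: a candidate call would then need 20 converted reads against a
  Poisson mean of 4, so "zero candidates with a nonzero mean" is a
  structural consequence of the threshold semantics rather than a lucky
  draw.

## Known limitations

* Editability is a reachability statement under the geometric criteria; the
  package does not predict editing efficiency, bystander edits, or TALE
  protein behaviour (RVD composition, mismatch tolerance).
* The off-target caller quantifies substitutions only; indel quantification
  and nuclear off-target analysis are out of scope.
* Absolute off-target averages from published cell experiments depend on
  the exact caller settings used on the deposited raw data and are not
  reproducible from synthetic reads; the package instead proves its
  statistics recover programmed truths within binomial error.
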