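# ddcbetools

Target design and off-target analysis for DddA-derived cytosine base
editors (DdCBEs) in organellar genomes.

DddA's deaminase domain converts C·G to T·A in double-stranded DNA, with a
strong preference for cytosines in a 5'-TC context. The canonical editor is
**dimeric**: two TALE arrays, each carrying an inactive half of the
deaminase, must bind convergently on opposite strands so that a 14–18 bp
spacer between their sites is edited. A **monomeric** editor (mDdCBE) fuses
a non-toxic full-length deaminase to a single TALE and edits offsets 1–18
downstream of the site's 3'-terminal thymidine, most efficiently at offsets
4–11. Because the dimeric geometry needs two thymidine-flanked 14–20 bp
TALE sites plus a constrained spacer, a fraction of the TC motifs in a
genome is reachable only monomerically — on the human mitochondrial
reference (rCRS, NC_012920, shipped with the package), 8.4% of all 1,817 TC
motifs.

The package provides, as plain tidyverse-style functions returning tibbles:

* **Targetability scan** — `find_tc_motifs()`, `enumerate_tale_sites()`,
  `find_ddcbe_designs()`, `find_mddcbe_designs()`, and
  `editability_report()`, which classifies every motif by the architecture
  that can reach it and tabulates the sensitivity of the result to the open
  conventions (circular vs linear origin handling, window anchored at the
  motif's C vs T, spacer membership rule).
* **Design for a target** — `design_for_target()` enumerates every design
  covering a chosen cytosine and ranks monomeric designs by placement of
  the target inside the preferred 4–11 editing window.
* **Conversion calling** — `pileup_conversions()` computes per-position
  C→T / G→A conversion rates from aligned reads (SAM/BAM);
  `quantify_on_target()` restricts them to a window as percentages;
  `summarize_offtarget()` applies the SNV (≥ 50%) and on-target exclusions
  and averages all retained C/G positions genome-wide, listing ≥ 0.1%
  candidates separately.
* **Window profiling** — `align_profile_to_site()` and
  `aggregate_window()` recover the monomeric editing window from
  per-position editing frequencies.
* **Simulation** — `simulate_genome()` (planted motifs/designs) and
  `simulate_reads()` (pre-aligned reads with programmed substitution
  fractions, SNVs and sequencing error) make every stage testable without
  external data, deterministically per seed.

Result objects carry `tidy()`, `glance()` and `autoplot()` methods. A
JSON-config entry point `dd_run()` ties the stages together, and a thin CLI
wrapper ships at `system.file("scripts", "ddcbetools", package = "ddcbetools")`.

## Worked example

```r
library(ddcbetools)

g <- rcrs_genome()            # packaged human mitochondrial reference
g
#> <dd_genome> NC_012920: 16,569 bp, circular
#> GATCACAGGTCTATCACCCTATTAACCACTCACGGGAGCTCTCCATGCATTTGGTATTTT...

rep <- editability_report(g)
rep
#> <dd_editability> NC_012920 (16,569 bp, circular)
#>   TC motifs: 1817 | DdCBE-editable: 1665 | mDdCBE-editable: 1817
#>   mDdCBE-only: 152 (8.4% of all motifs)
```

Every TC motif is reachable by a monomeric editor somewhere, 1,665 of the
1,817 sit inside at least one valid dimeric spacer, and 152 (8.4%) can be
edited **only** monomerically. `rep$sensitivity` tabulates the same counts
under the alternative conventions (linear topology raises the fraction to
8.7%; counting a boundary motif by its C alone rather than the whole
dinucleotide lowers it to 4.6%).

The mitochondrial tRNA-Cys gene (rCRS 5761–5826) contains such
monomeric-only cytosines. Asking for designs against one of them:

```r
design_for_target(g, 5777, "-", one_based = TRUE)
#> # A tibble: 12 × 12   (monomeric designs only; no dimeric pair exists)
#>   design_type site_start site_end site_strand target_offset in_preferred_window
#> 1 monomeric         5778     5792 -                       2 FALSE
#> 2 monomeric         5778     5793 -                       2 FALSE
#> ...
```

Twelve single-TALE designs cover the target; no dimeric pair does.

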