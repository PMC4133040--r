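---
title: "Scanning, dissecting and modeling posterior neural enhancers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning, dissecting and modeling posterior neural enhancers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crmscan)
```

## The biological problem

In ascidian embryos, FGF induces neural fate in two ectodermal precursor
pairs at the 32-cell stage. The posterior pair (the b6.5 lineage, which goes
on to form the dorsal tail nerve cord and dorsal epidermal midline) further
requires two direct FGF targets, the TGF&beta; ligand Nodal (signaling
through Smad2/3) and the homeodomain factor Otx, to switch on the lineage
markers *Msxb* and *Delta2*. This regulatory logic predicts that b6.5
enhancers should co-cluster binding sites for Otx (core word GGATTA, with
the degenerate variant GATTA), a Fox factor proposed as the Nodal nuclear
co-factor (AAACA, reverse complement TGTTT) and Smad (the AGAC Smad Binding
Element, SBE). `crmscan` implements that prediction as a reusable pipeline:
a consensus-word motif engine, a windowed co-occurrence scanner with an
escalating stringency ladder, a phylogenetic footprinting filter, an
in-silico enhancer mutagenesis engine, a Boolean model of the upstream
network, and a synthetic-locus generator that provides ground truth for all
of it.

## The motif engine

Motifs are literal IUPAC consensus words, never position weight matrices:
the field's published enhancer dissections of this system used core words
only, and the package follows that choice. `find_sites()` reports every
occurrence on both strands with overlapping-hit semantics (the overlapping
Fox pair AAACAAACA reports two hits), `N` in a sequence matches nothing
(an unknown base is evidence for nothing), and a hit occupying the same
interval on both strands is reported once, on `+`.

Counting is class-aware. Each motif carries a specificity class
(`strict` GGATTA > `canonical` GATTA/AAACA/AGAC > `non-canonical`
GHATTA/AACA) and `count_by_class()` suppresses a hit that overlaps a
same-factor hit of a more specific class, so a genomic site is counted
once, at its most specific class. This is what makes the AACA words inside
an AAACA site invisible, matching how published site maps color such
regions: the overlapping canonical pair counts as two Fox sites, not two
canonical plus two degenerate.

```{r}
count_by_class("AAACAAACA")
```

## The co-occurrence scanner and its ladder

`crm_scan()` slides a 300 bp window (the width used to delimit candidate
regions in this system; tunable via `scan_config()`) at 1 bp steps. A window
qualifies when it contains at least one strict Otx word, one Fox word and
one SBE (the base requirement), plus, at ladder level *L*, at least *L*
additional degenerate GATTA words. Raising *L* is the stringency ladder that
reduced 15 candidate regions to 7 and then 4 at the *Msxb* locus.
Qualifying windows that overlap or abut are merged into maximal regions;
counts are recomputed on the merged interval and each region is labeled with
the highest level it still satisfies.

Numerical choices worth stating:

* **Step size** defaults to 1 bp. The published scan does not state a step;
  exhaustive offsets are cheap at 50 kb and remove tiling artifacts.
* **"Additional" GATTA** excludes GATTA words nested inside a strict GGATTA
  hit, since that GATTA is the same physical site that satisfied the base
  requirement. The published wording is ambiguous on this point, so it is a
  switch (`count_nested_gatta`).
* **Locus tails** shorter than one window are scanned as a truncated window
  and flagged, never silently dropped.
* **Coordinates** are 0-based half-open everywhere internally and in BED
  output; GFF3 export is the sole 1-based inclusive surface.

A caveat on region counts: because qualifying windows are merged, raising
the ladder level guarantees that the region *footprint* shrinks (every
level-(L+1) region lies inside a level-L region) but a single region can
split in two, so the region *count* is not strictly monotone on arbitrary
backgrounds. The tests assert the footprint form.

## Conservation filter

"The orthologous region harbors a similar combination of binding sites" is
operationalized in its weakest defensible reading: some window of the
ortholog satisfies the same base requirement and ladder level as the focal
region (`combination_conserved()`). No alignment is computed — orthology is
the caller's responsibility — and per-class count matching, spacing and
order are deliberately not required, because the published filter does not
state them; a stricter per-class count mode is available via
`match_counts = TRUE`. When several related genomes are supplied,
`filter_candidates()` takes the conjunction: every ortholog must pass.

## The mutation series

`mutation_recipe()` encodes the published mutant notation: an IUPAC target
located on both strands and an equal-length template whose lower-case
letters are the substituted bases (`GATTA -> GcTTA`, `AGAC -> ctAC`,
`AAACAAACA -> AAACgAACA`, `AACA -> AgCA`). Minus-strand hits are rewritten
in reverse-complement space so the destroyed word is the motif itself.
Overlapping rewrites that disagree at a shared position are an error, never
last-writer-wins. `verify_knockout()` guards the implicit assumption of any
mutant series: the targeted class reaches zero and no new site of any
tracked motif is created by the rewrite.

Two interpretive choices, stated openly:

* The all-Otx construct (`Msxb-I`, published as `GNATTA -> GNcgTA`) is
  applied as `GHATTA -> GHcgTA` plus `GATTA -> GcgTA`, so canonical sites
  not preceded by G are destroyed too; on a G-preceded site both recipes
  write the same bases and compose without conflict.
* The sensitized double mutant `Msxb-F` combines the canonical-Otx recipe
  with the one-change-per-core Fox recipe (`AAACAAACA -> AAgCAAgCA`). The
  published per-base choice lives in supplementary material that is not
  redistributed here; any recipe destroying both overlapping Fox cores is
  equivalent at the level this package models.

## The Boolean network

`grn_simulate()` encodes the FGF/Otx/Nodal network as Boolean update rules
over one cell per ectodermal lineage (plus, for "ectopic expression"
observations, an uninduced reporter cell). Two modeling choices do real
work:

* **Two-tier Nodal signaling.** *Msxb*/*Delta2* require the high, autocrine
  tier (ligand expressed in the responding cell), while *Chordin* responds
  to a low, ectoderm-wide tier (ligand anywhere in the ectoderm). This
  reconciles *Chordin*'s Nodal-dependent anterior expression with the
  absence of anterior *Msxb* in controls. The published work implies but
  never names this distinction; it is a modeling choice here.
* **Two-phase Nodal dynamics.** The first update uses an initiation rule
  (direct FGF induction, restricted to the posterior lineage) and later
  updates a maintenance rule (Otx together with Nodal autoregulation),
  mirroring the separation between initial induction at the 32-cell stage
  and maintenance at the 64-cell stage.

On update order: a strictly synchronous scheme makes the Nodal
autoregulation loop (ligand &rarr; signal &rarr; ligand) oscillate with
period two and never converge. The package therefore updates nodes in a
fixed declared order within each step, each rule reading the newest
available values (signal-transduction nodes effectively see the previous
step's ligand state). This is deterministic, reaches a fixed point within
six steps for every tabulated context, and is the only deviation from a
textbook synchronous network.

The shipped observation table (`default_observations()`) transcribes ~55
qualitative outcomes from the published perturbation panels, including the
ligand itself as a marker and uninduced-ectoderm rows; the extra rows
relative to a minimal table exist so that deleting any single regulatory
edge (`delete_edge()`) breaks at least one observation — the edge-necessity
property the tests assert. Loss-of-function reagents (morpholino and
dominant-negative Otx) are modeled identically as forcing the node
inactive; electroporation mosaicism, blastomere-level patterning and the
non-additivity of combined Otx/Nodal overexpression are out of scope.

## The synthetic-locus generator, and what a green test establishes

`generate_locus()` draws an independent-letter background at 65% AT — the
composition regime of ascidian non-coding DNA — and plants CRMs as ordered
motif words with chosen spacers. With `exclusion = TRUE`, accidental hits of
the tracked motifs are removed by rejection-resampling of non-planted
positions, so the planted sites are provably the only ones.
`diverge_ortholog()` mutates only outside planted words and re-applies the
same scrubbing, because a single background substitution can otherwise
upgrade a planted GATTA to a strict GGATTA and silently change the ladder
arithmetic.

The generator is a stated world, not a claim about genomes: no dinucleotide
structure, no repeats, no neutral-evolution model, divergence rates chosen
(default 30% substitutions) to represent "diverged beyond alignability"
rather than any calibrated distance. Consequently, perfect recovery under
exclusion sampling establishes that the scanner finds exactly what the
ladder defines — a correctness statement about the pipeline, not an
accuracy statement about real loci, where background hits and chance
clusters exist by construction.

### The enhancer stand-ins

The published enhancer sequences live in PDF supplementary files and are
not redistributed. `synthetic_enhancer()` therefore builds labelled
synthetic stand-ins by construction: scrubbed 65%-AT background with the
published per-class composition planted exactly — 3 canonical Otx, the
GAATTA non-canonical site, the AAACAAACA overlapping Fox pair, 3
stand-alone degenerate Fox and 4 SBEs in 273 bp for the minimal enhancer,
and 6/5/6, 5/3/3 and 6/7/7 (Otx/Fox/SBE) for the three full-length
regions. The stand-in construction additionally requires that the published
mutation recipes are clean knockouts on it (no collateral site creation),
a property the real sequences had. Count assertions on these fixtures
verify the annotation machinery against the published compositions; they do
not, and cannot, verify the genomic sequences themselves.

## Worked example

```{r}
enh <- synthetic_enhancer("msxb_B")
annotate_region(enh, name = "msxb_B (synthetic stand-in)")

ser <- build_series(enh)
ser
verify_knockout(ser[["Msxb-L"]])
```

```{r}
consistency_score()
perturbation_screen(marker = "Epi")
```

## Known limitations

* Consensus words only; no affinity model, no p-values for cluster
  enrichment (none were used in the source analysis this package
  re-implements).
* The 15/7/4 genome-scale region counts at the real *Msxb* locus depend on
  an external ~50 kb genome slice and on unstated window/strand
  conventions; the package exposes the relevant switches
  (`count_nested_gatta`, `strands`, `window_bp`) but ships no genome.
* The Boolean model has one cell per lineage and no spatial gradients; it
  reproduces qualitative ON/OFF outcomes, not expression levels or
  penetrance percentages.
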