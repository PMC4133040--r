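# crmscan

Combinatorial binding-site scanning, in-silico enhancer mutagenesis and
Boolean network logic for ascidian posterior neural enhancers.

## The problem

In ascidian embryos, the posterior neural lineage (b6.5) is specified
downstream of FGF by two of its direct targets acting together: the TGFβ
ligand Nodal, signaling through Smad2/3 with a Fox factor as proposed DNA
co-factor, and the homeodomain factor Otx. Enhancers driving the lineage
markers *Msxb* and *Delta2* should therefore co-cluster three short
consensus words within a few hundred base pairs:

* **Otx**: `GGATTA` (strict), `GATTA` (degenerate), `GHATTA` (non-canonical)
* **Fox**: `AAACA` (reverse complement `TGTTT`), `AACA` (degenerate)
* **Smad Binding Element (SBE)**: `AGAC`

`crmscan` turns that prediction into a tested pipeline for anyone dissecting
cis-regulatory modules with literal consensus words:

1. **Motif engine** — exact IUPAC matching on both strands with
   overlapping-hit semantics and most-specific-class counting
   (`find_sites()`, `count_by_class()`, `annotate_region()`).
2. **Co-occurrence scanner** — a sliding 300 bp window requiring at least
   one strict Otx + one Fox + one SBE, plus an escalating "stringency
   ladder" of *L* additional degenerate `GATTA` words; qualifying windows
   merge into candidate regions (`crm_scan()`, `scan_config()`).
3. **Conservation filter** — phylogenetic footprinting: a candidate
   survives when each supplied orthologous sequence carries the same site
   combination in one window (`combination_conserved()`,
   `filter_candidates()`).
4. **Mutation series** — site-destroying recipes in the published notation
   (`GATTA→GcTTA`, `AGAC→ctAC`, ...), applied on either strand with
   knockout verification (`mutation_recipe()`, `build_series()`,
   `verify_knockout()`).
5. **Boolean network** — the FGF/Otx/Nodal circuit as a two-phase Boolean
   model with a perturbation vocabulary (MEK/receptor inhibitors,
   morpholino, dominant-negative, overexpression), scored against a shipped
   table of qualitative outcomes (`grn_simulate()`, `consistency_score()`).
6. **Synthetic loci** — seeded 65%-AT background with planted site
   clusters and site-preserving "orthologs", giving ground truth for
   scanner recovery benchmarks (`generate_locus()`, `diverge_ortholog()`,
   `recovery_experiment()`).

The published enhancer sequences live in PDF supplements and are not
redistributed: `synthetic_enhancer()` ships labelled synthetic stand-ins
constructed to the published per-class compositions (see the vignette for
what that does and does not establish).

## Worked example

```r
library(crmscan)

enh <- synthetic_enhancer("msxb_B")   # 273 bp stand-in
annotate_region(enh, name = "msxb_B")
#> <region_report> msxb_B (273 bp)
#>         motif_name factor         klass count
#>      Otx-canonical    Otx     canonical     3
#>  Otx-non-canonical    Otx non-canonical     1
#>      Fox-canonical    Fox     canonical     2
#>  Fox-non-canonical    Fox non-canonical     3
#>                SBE   Smad     canonical     4
```

Three canonical Otx words, the overlapping canonical Fox pair
(`AAACAAACA`), four SBEs, one non-canonical `GAATTA` Otx word and three
stand-alone degenerate Fox words — the published composition of the minimal
active enhancer fragment. The mutation series then destroys each class in
turn and verifies each knockout is site-specific:

```r
ser <- build_series(enh)
verify_knockout(ser[["Msxb-L"]])     # all four SBEs destroyed, nothing created
#> <knockout_check> PASS
```

Scanning a synthetic locus shows the stringency ladder at work — planted
clusters carrying 0, 1 and 2 extra degenerate Otx words drop out one by one
as the level rises, the same 15→7→4-style reduction used to find the real
enhancers:

```r
spec <- locus_spec(20000, plants = list(crm_plant(3000, extra_gatta = 0),
                                        crm_plant(8000, extra_gatta = 1),
                                        crm_plant(14000, extra_gatta = 2)))
loc <- generate_locus(spec, seed = 1)
sapply(0:2, function(L) nrow(crm_scan(loc$seq, scan_config(ladder_level = L))$regions))
#> [1] 3 2 1
```

And the Boolean network reproduces every tabulated perturbation outcome:

```r
consistency_score()
#> <grn_consistency> 55/55 observations matched (score 1.000)
```

## Command line

A thin subcommand CLI wraps the same functions:

```sh
Rscript inst/scripts/crmscan-cli.R scan locus.fa --level 2 --out out/
Rscript inst/scripts/crmscan-cli.R annotate enhancer.fa --out out/
Rscript inst/scripts/crmscan-cli.R mutate enhancer.fa --out out/
Rscript inst/scripts/crmscan-cli.R grn
```

## Acceptance script

`scripts/acceptance.R` re-runs the whole pipeline from scratch under a
seed — the ladder scan on a freshly generated locus, the four-candidates /
one-conserved filter, annotation and the full mutation series on the
stand-ins with knockout verification, the network consistency score, and
the planted-CRM recovery benchmark — and writes its JSON summary to
`--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
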