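Package: crmscan
Title: Combinatorial Binding-Site Scanning and Boolean Network Logic for
    Ascidian Posterior Neural Enhancers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting and dissecting cis-regulatory modules that
    integrate Otx, Fox and Smad (Nodal effector) inputs, as used to isolate
    posterior neural lineage enhancers in ascidian genomes. Provides an IUPAC
    consensus motif engine with exact overlapping-hit semantics on both
    strands, a sliding-window co-occurrence scanner with an escalating
    stringency ladder and region merging, a phylogenetic footprinting filter
    that retains regions whose orthologous sequence carries the same site
    combination, an in-silico site-directed mutagenesis engine reproducing
    enhancer mutation series, a synchronous Boolean model of the FGF/Otx/Nodal
    posterior neural gene regulatory network scored against qualitative
    perturbation outcomes, and a seeded generator of AT-rich synthetic loci
    with planted site clusters for benchmarking recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
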