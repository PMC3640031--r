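Package: soilniche
Title: Two-Niche Comparison of Soil Microbial Communities from
    Phylogenetic Microarrays and Gel Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Compares microbial communities between two soil niches (for
    example inside versus outside a truffle brule) using two molecular
    profiling arms.  For phylogenetic 16S rRNA microarrays it implements
    probe-pair response scoring, quantile-based Stage1/Stage2 OTU
    presence calling with a cross-hybridization penalty, spike-in
    intensity scaling and trimmed-mean probe-set summarization, followed
    by per-taxon relative-richness tables, per-OTU differential intensity
    tests with fold-change heatmap selection, discriminative-taxon
    summaries, and a principal-component community-structure test with an
    exact enumeration null.  For denaturing-gradient gel fingerprints it
    provides Pearson lane similarity, UPGMA clustering with newick
    export, and stratified permutation tests of within- versus
    between-group similarity.  A synthetic-data generator with known
    ground truth (planted presence, fold-change and band effects) makes
    every stage testable without the original hybridization data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
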