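Package: mangroveGBM
Title: Gene Body Methylation Evolution and Salt-Stress Response in Mangroves
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the evolution of gene body methylation (gbM)
    across a three-pair mangrove/non-mangrove species design with an outgroup.
    Implements binomial site-level methylation calling against a bisulfite
    conversion-rate null with Benjamini-Hochberg FDR control, replicate
    consensus, gene classification into body-methylated (BM), mCHG, mCHH and
    unmethylated (UM) categories, hierarchical maximum-parsimony ancestral
    state reconstruction with outgroup tie resolution, per-branch gbM gain and
    loss rates, a convergence-at-conserved-sites classifier for genes and
    individual CG sites, salt-stress differentially methylated position (DMP)
    and gene (DMG) calling, expression-robustness statistics based on the
    absolute normalized expression difference, and simulators that generate
    every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
biocViews: Epigenetics, DNAMethylation, Phylogenetics, Software
RoxygenNote: 7.3.3
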