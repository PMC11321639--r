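Package: cfpattern
Title: Cell-Free DNA Fragmentation Patterns over Regulatory Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes ten cell-free DNA (cfDNA) fragmentation-pattern feature
    sets (fragment length profile, fragmentation entropy, size ratios and
    distributions, coverage, fragment ends, orientation-aware fragmentation,
    integrated fragmentation score, windowed protection score, and end motifs)
    over open-chromatin or other genomic region sets, corrects GC bias by
    locally weighted regression, trains per-pattern linear support vector
    machine classifiers, and stacks their out-of-fold probabilities into an
    Integrated Fragmentation Pattern (IFP) ensemble for cancer detection and
    tissue-of-origin calling. Includes screening of classifier-important
    regulatory regions, differential fragmentation signatures with gene
    mapping, and a synthetic cfDNA cohort simulator so that every stage is
    testable without external sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    e1071,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
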