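Package: clonesift
Title: Enrichment Analysis of CDR3 Clonotypes from Multi-Round Library Selections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for intracellular antibody (intrabody) library
    selections read out by amplicon sequencing. Simulates multi-round FACS
    selections of an scFv/VH library (power-law clone abundances, per-clone
    multiplicative selection, multinomial read sampling, indexed 100-base
    reads), demultiplexes indexed reads into per-round CDR3 clonotype count
    tables, calls enriched clonotypes with a resampling two-class rank test and
    permutation-estimated false discovery rate, applies an ordered filter
    cascade (presence in both endpoint libraries, FDR, stop-codon/frame,
    monotonic frequency increase, 100-fold enrichment), clusters survivors into
    antibody families by complete linkage on a length-aware normalized Hamming
    distance, and provides the companion phenotype statistics (degranulation
    release percentage, MFI stimulation index, Jarque-Bera and D'Agostino
    normality/skewness tests, two-component normal mixture fit).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml,
    Biostrings
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
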