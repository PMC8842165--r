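Package: mamthscreen
Title: Analysis of Pooled Membrane Two-Hybrid Interaction Screens and
    CFTR Functional Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis toolkit for pooled mammalian membrane
    two-hybrid (MaMTH-HTS) protein-protein interaction screens and their
    downstream validation assays. Provides exact k-mer assignment of
    sequencing reads to an ORFeome prey library with CPM normalization,
    count-threshold candidate-interactor calling with replicate-overlap
    reporting, rank-product identification of promiscuous "frequent flier"
    preys across control screens with permutation p-values and
    Benjamini-Hochberg adjustment, bait-versus-bait interactome set
    comparison and edge-list export, high-content siRNA trafficking-screen
    analysis (image QC, 5x5 well-neighbourhood Z-scores, replicate
    aggregation and enhancer/inhibitor/ambiguous gene calls), and
    functional-assay statistics for FLIPR membrane-potential traces,
    forskolin-induced organoid swelling, Ussing-chamber recordings and
    Western-blot quantification. A seedable synthetic-data module
    generates reads, count tables, plate images summaries and assay
    traces with the enrichment and noise structure these screens assume,
    so the whole pipeline is testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
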