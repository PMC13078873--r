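Package: redoxQuant
Title: Site-Level Cysteine Redoxome Quantification and Differential
    Oxidation Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies reversible cysteine oxidation from paired
    half-sample TMT reporter data (oxidized-enriched vs total channels),
    computes per-site oxidation percentages, calls differentially
    oxidized cysteines with a composite t-test / relative-increase /
    top-percentile rule, ranks proteins by called-site count, maps
    called sites onto protein domains, and performs probability-logo
    style binomial log-odds motif analysis of flanking sequences with a
    Bonferroni-corrected significance threshold. Includes a seeded
    synthetic-experiment generator with planted oxidation effects,
    a hotspot protein and a positional sequence bias, so the whole
    pipeline is testable without mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    Biostrings,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'io.R'
    'quantify.R'
    'differential.R'
    'motif.R'
    'synthetic.R'
    'pipeline.R'
    'redoxQuant-package.R'
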