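Package: switchjunction
Title: Class Switch Recombination Junction Architecture and Somatic Hypermutation Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the fragment architecture of chimeric switch-junction
    amplicons against germline donor and acceptor switch-region references,
    resolves every junction boundary as blunt, microhomology or insertion,
    classifies junctions into the simple/compound taxonomy with atypical flags
    (microdeletion, long microhomology, inversion) and a per-sequence complexity
    score, and profiles somatic hypermutation clone sets (substitution spectrum,
    per-bp frequency, RGYW/WRCY and WA/TW hotspot motifs). Ships the exact
    statistics used in such studies (two-tailed Fisher exact test, Pearson
    chi-squared with small-expected-count pooling, ratio normalisation with
    error propagation) and a synthetic-data generator that emits repeat-rich
    references, junction reads and SHM clone sets with exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
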