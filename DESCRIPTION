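Package: cmfscan
Title: Screening Genomes Against a Core Set of Minimal Functions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives a core set of minimal functions (CMF) from annotated
    synthetic minimal genomes, screens prokaryotic genome annotations
    (isolate assemblies or metagenome-assembled genomes) for presence or
    absence of each core function, and analyses the resulting binary
    matrix: per-genome adherence and per-gene missingness summaries, rank
    tests and Fisher's exact test, Jaccard and binary-Euclidean distances,
    Ward clustering, principal component analysis, logistic PCA for binary
    profiles, PERMANOVA, and Kendall correlation of adherence with
    completeness estimates. Includes a synthetic-cohort generator with
    known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
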