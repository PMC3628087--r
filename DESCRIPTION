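Package: kataegisr
Title: Detection and Characterization of Kataegic Mutation Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects kataegis (localized strand-coordinated hypermutation at
    C:G pairs) in per-clone somatic substitution catalogs. Intermutational
    distances are split into proximal and distal groups by one-dimensional
    k-means on the log scale, a cluster-calling threshold is derived as the
    distal-group quantile excluding a chosen fraction of distal distances,
    and maximal runs of closely spaced mutations are called as clusters.
    Includes a Monte Carlo null model for randomly scattered mutations,
    pyrimidine-oriented substitution spectra, strand-polarity scoring,
    minus-2/minus-1 sequence-context position frequency matrices with
    genomic-background normalization, Sandelin-Wasserman motif similarity
    with a permutation p-value, and a synthetic-data generator that emulates
    AID/APOBEC-mutagenized yeast genomes with planted clusters and known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
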