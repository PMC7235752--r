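Package: structphylo
Title: Structure-Partitioned Phylogenomic Signal Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for asking whether protein sites in different structural
    environments carry different phylogenetic signals. Partitions concatenated
    protein alignments into solvent-accessibility and secondary-structure
    classes via Henikoff-weighted consensus sequences, fits single-matrix
    (GTR-style and empirical) and profile-mixture amino-acid substitution
    models on fixed candidate topologies with a generic n-state reversible
    likelihood engine, detects decisive sites from per-site log-likelihood
    differences, compares fitted exchangeability matrices by classical
    multidimensional scaling with a random-subsampling sampling-variance
    null, diagnoses compositional heterogeneity (GARP/FYMINK ratios and
    back-translated nucleotide axes), recodes amino acids (Dayhoff six-state
    and binary purine/pyrimidine), and simulates structure-partitioned
    alignments with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    withr,
    Matrix
Config/testthat/edition: 3
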