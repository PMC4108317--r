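Package: metatelescope
Title: Two-Projection Profile-HMM Homology Search Through Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a "metagenomic telescope": a remote-homology search
    strategy in which a profile hidden Markov model built from a seed protein
    family is first projected onto open reading frames extracted from
    metagenome contigs, the resulting matches are density-clustered (OPTICS)
    and turned into new profile HMMs, and those new models are projected back
    onto model-organism proteomes to surface telescopic hits absent from the
    direct search. Includes six-frame ORF extraction, progressive multiple
    alignment with affine-gap profile alignment, profile-HMM construction with
    Henikoff position-based weighting, forward and Viterbi scoring in log
    space, Gumbel E-value calibration, OPTICS ordering with DBSCAN-style
    cluster extraction, and a synthetic benchmark generator with known
    transitive-homology ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
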