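Package: lumpability
Title: Tests for Lumpability of Nucleotide Substitution Processes under Recoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical tests that decide whether a stationary, reversible and
    homogeneous (SRH) nucleotide substitution process remains Markovian after
    the four-letter alphabet is recoded (lumped) to three or two letters, for
    example RY-recoding into purines and pyrimidines. Implements the catalogue
    of the 13 possible recoding schemes, closed-form estimation of the pairwise
    SRH model from a divergence matrix, the lumpability index with its
    parametric-bootstrap test, a chi-squared test for lumpability of Markov
    chains, and a likelihood-ratio test with linearly constrained maximum
    likelihood. Includes Monte Carlo machinery for calibration and power
    experiments, sequence simulation on trees, all-pairs testing of multiple
    sequence alignments, and quantification of the branch-length bias caused
    by non-lumpable recoding.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    optparse
Config/testthat/edition: 3
biocViews: Phylogenetics, StatisticalMethod, Software
RoxygenNote: 7.3.3
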