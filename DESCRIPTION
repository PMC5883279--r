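Package: chlorosel
Title: Positive Selection and Convergent Evolution in Chloroplast
    Protein-Coding Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Codon-model likelihood analysis of positive selection and
    convergent amino-acid evolution in multi-gene chloroplast data sets.
    Implements Goldman-Yang codon substitution models with F3x4
    frequencies (one-ratio M0, branch, M8/M8a site and branch-site
    model A variants), likelihood-ratio tests with Benjamini-Hochberg
    false discovery rate control, Bayes empirical Bayes identification
    of positively selected sites, marginal ancestral amino-acid
    reconstruction under empirical substitution matrices, and a Poisson
    test comparing observed to model-expected counts of parallel and
    convergent substitutions between species pairs. Includes a
    synthetic-data generator for codon and amino-acid alignments and an
    end-to-end pipeline over per-gene alignments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
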