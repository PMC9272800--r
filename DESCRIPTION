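Package: hicmrf
Title: Bayesian Calling of Significant Hi-C Interactions with a Hidden
    Markov Random Field
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies Hi-C and micro-C contact-matrix entries into noise,
    true-signal and (optionally) false-signal components using a
    zero-inflated Poisson mixture whose component means are corrected for
    genomic distance, GC content, transposable-element content and DNA
    accessibility biases. Spatial dependency between neighbouring bin pairs
    is modelled with a Potts hidden Markov random field; the intractable
    Potts normalizing constant is handled with an Approximate Bayesian
    Computation step inside a Metropolis-within-Gibbs sampler. Includes a
    synthetic-data generator reproducing the model's generative process,
    empirical-Bayes prior construction, a modified deviance information
    criterion for choosing the number of mixture components, interaction
    calling with BEDPE export, and characterization of calls against TADs
    and promoter annotation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
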