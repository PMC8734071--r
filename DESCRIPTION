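Package: chromstack
Title: Stacked Multivariate Bernoulli Hidden Markov Models for Universal
    Chromatin-State Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains a single ("full-stack") hidden Markov model with
    multivariate Bernoulli emissions over many binarized epigenomic datasets
    stacked as features, producing one universal chromatin-state annotation
    of the genome. Implements Poisson-test binarization of aligned-read
    tracks at 200-bp resolution, chunked Baum-Welch training with
    per-iteration segment subsampling, pseudo-counts and a max-renormalized
    emission-product stabilization for large feature sets, max-posterior
    decoding, and a downstream state-characterization toolkit:
    base-resolution fold enrichments against external annotations,
    anchor-centred positional enrichments, sampled overlap probabilities
    against per-sample segmentations, AUROC evaluation of a segmentation's
    power to predict annotations, bp-normalized expression summaries,
    per-base signal averages, tissue-group differential-emission tests, and
    greedy Naive-Bayes selection of summary datasets. A seeded synthetic-data
    generator emulates every input class for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    GenomeInfoDb,
    Rcpp,
    data.table,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
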