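Package: haploLD
Title: Diversity, Linkage Disequilibrium and Recombination from Haploid
    Multilocus Sequence Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for population-genetic analysis of phased haploid
    sequence alignments such as conifer megagametophyte resequencing data.
    Classifies alignment columns (indel, multiallelic, singleton,
    parsimony-informative) under explicit missing-data policies; computes
    per-locus and per-population diversity summaries (Watterson's theta,
    nucleotide diversity, haplotype diversity, Tajima's D with
    beta-approximation significance), Hudson-style global FST, pairwise
    linkage disequilibrium (r2, D', exact tests with Bonferroni
    correction) and LD-based SNP pruning, Hill-Weir r2 decay and
    D'(t)=(1-r)^t decay fits with threshold-crossing distances, and
    pairwise composite-likelihood estimation of the population
    recombination rate rho = 4*Ne*r from Monte Carlo two-locus likelihood
    lookup tables. Includes a coalescent simulator with recombination,
    exponential growth and island migration that emulates a paired-end
    amplicon resequencing design, a resampling module quantifying the
    sample-size sensitivity of Tajima's D, interchange writers (STRUCTURE,
    LDhat-style sites/locs), and a reproducible full-analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    IRanges,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'seqio.R'
    'sites.R'
    'popstats.R'
    'fst.R'
    'ldcore.R'
    'lddecay.R'
    'rho_lookup.R'
    'rho_estimate.R'
    'simgen.R'
    'resample.R'
    'pipeline.R'
    'published.R'
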