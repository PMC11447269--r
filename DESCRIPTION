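Package: karstpop
Title: Conservation Genomics of Small, Inbred Populations
Version: 0.1.0
Authors@R:
    person("karstpop", "developers", email = "karstpop@example.org",
           role = c("aut", "cre"))
Description: Statistics for whole-genome conservation genomics of small,
    isolated populations, motivated by studies of karst-restricted langurs:
    nucleotide diversity and heterozygosity profiling, PLINK-style detection
    of runs of homozygosity and excess-homozygosity inbreeding coefficients,
    GERP-score based masked and realized genetic load with snpEff-style effect
    categories, ABBA-BABA D-statistics with weighted block-jackknife
    significance, a three-method selective-sweep consensus scan (theta-pi
    ratio, XP-EHH, Ka/Ks), private non-synonymous variant screens, and KING
    kinship classification. A fully seeded synthetic-data generator emits
    VCF/GFF3/score-track bundles with ground-truth records so that every
    estimator is testable without access to restricted sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
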