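Package: tetmut
Title: Mutation Enrichment at Differential 5-Hydroxymethylcytosine Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studying hypermutagenicity associated with
    loss of the TET2 dioxygenase. Classifies genomic loci by differential
    5-hydroxymethylcytosine (5hmC) and 5-methylcytosine (5mC) peak dynamics
    between wild-type and knockout conditions, tests somatic-mutation
    enrichment across those categories with footprint-normalised chi-squared
    statistics, summarises mutation spectra (pyrimidine-collapsed substitution
    classes and single-base indels), evaluates CpG-proximity of mutations
    against a spacing-based null model, computes HPRT 6-thioguanine
    fluctuation-assay mutation frequencies with plating-efficiency
    normalisation, and compares mutational burden between cohorts. A seeded
    synthetic-data generator produces truth-labelled genomes, peak sets,
    variant sets, cohorts and assay counts so the whole pipeline runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
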