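Package: resistscan
Title: Catalog-Driven Monitoring of Insecticide-Resistance Mutations in
    Pest Resequencing Data
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Geographic monitoring of target-site insecticide-resistance
    mutations and metabolic-resistance copy-number variation from
    population resequencing data of the fall armyworm (Spodoptera
    frugiperda) and similar pests. Screens multi-sample VCF genotypes
    against a curated resistance-mutation catalog with codon-level
    consequence annotation (missense, in-frame indels, frameshifts with
    premature-stop calling), summarises carrier proportions per
    population and cohort, estimates Weir-Cockerham F_ST between
    resistant and susceptible groups with a same-length-locus
    genome-resampling empirical null, contrasts gene-family copy-number
    burden between cohorts with a two-tailed Fisher exact test
    implemented from first principles, and provides analytic
    allele-detection power calculations. Includes synthetic-data
    generators (Hardy-Weinberg genotypes, Balding-Nichols background
    differentiation, Poisson copy-number events) with recorded ground
    truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    jsonlite,
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    withr
biocViews: PopulationGenetics, VariantAnnotation, CopyNumberVariation,
    Genetics, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'catalog-io.R'
    'consequence.R'
    'screen.R'
    'fst.R'
    'burden.R'
    'power.R'
    'simulate.R'
    'table1-fixture.R'
    'pipeline.R'
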