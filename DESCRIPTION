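Package: coalSFS
Title: Coalescent Demographic Inference from 2D Minor-Allele Site Frequency Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring multi-taxon divergence histories from
    RAD-seq style SNP data via the folded two-dimensional minor-allele site
    frequency spectrum (2D-mSFS). Includes a backward-in-time coalescent
    simulator of biallelic genotypes under divergence / size-change /
    recent-migration models (also used as the Monte-Carlo engine for expected
    spectra), Stacks-style site filtering, within-population missing-data
    bootstrap completion, composite-likelihood expectation-conditional-
    maximization (ECM) fitting with AIC model selection, parametric bootstrap
    confidence intervals, and an allometric seed-dispersal-distance
    calculator for avian dispersers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    Rcpp,
    yaml,
    jsonlite,
    vcfR,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'models.R'
    'catalog.R'
    'coalSFS-package.R'
    'coalsim.R'
    'dispersal.R'
    'sfs.R'
    'fit.R'
    'experiments.R'
    'pipeline.R'
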