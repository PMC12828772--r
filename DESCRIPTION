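Package: tmeSubtyper
Title: Cell-Type-Composition Subtyping of Bulk Prostate Cancer RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the cellular composition of bulk prostate tumor
    RNA-seq samples by constrained weighted least-squares deconvolution
    against cell-type reference profiles, discovers composition subtypes
    (TCE, EPCE, TASCE) by resampling consensus clustering with partitioning
    around medoids, trains and applies a linear discriminant subtype
    classifier, quantifies interpatient, interfocal and intrafocal
    heterogeneity of multifocal tumors with cosine similarity, and relates
    subtypes to Gleason grade, pT stage and time to biochemical recurrence
    with Kaplan-Meier, log-rank and Cox proportional-hazards models. A
    synthetic cohort generator with known ground truth supports validation
    of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    cluster,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'association.R'
    'classifier.R'
    'deconvolution.R'
    'expression_io.R'
    'heterogeneity.R'
    'outcome.R'
    'pipeline.R'
    'simulate.R'
    'subtyping.R'
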