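Package: erpmed
Title: Polygenic Scoring, ERP Phenotype Clustering, and Causal Mediation for
    Psychotic-Symptom Endophenotype Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline linking common genetic variation to
    positive psychotic symptoms through a neurophysiological intermediate
    phenotype. Provides genotype quality control (minor allele frequency, call
    rate, exact Hardy-Weinberg test, heterozygosity, method-of-moments
    relatedness, ancestry principal components), clump-and-threshold polygenic
    risk scoring from discovery GWAS summary statistics, K-means clustering of
    six event-related potential (ERP) measures with V-fold cross-validated
    selection of the number of clusters and labelling of a "globally impaired"
    cluster, logistic association testing with Nagelkerke incremental pseudo
    R-squared and false-discovery-rate adjustment, and regression-based
    counterfactual mediation analysis (natural direct and indirect effects,
    proportion mediated, bias-corrected bootstrap confidence intervals, and
    sensitivity analysis to unmeasured confounding). A synthetic-cohort
    generator with block linkage disequilibrium and a configurable
    exposure-mediator-outcome structure makes every stage testable without
    access to individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
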