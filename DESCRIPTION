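Package: chemodiscrim
Title: Chemometric Discrimination of GC/MS Metabolite Profiles with
    PLS-DA Validation and Combination Synergy Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for two-class discrimination of GC/MS relative-abundance
    metabolite profiles: abundance-cutoff feature filtering, z-score
    standardization, hierarchical clustering, principal component analysis
    with explained-variance reporting, Pearson-correlation-cluster feature
    selection, and a from-scratch NIPALS PLS-DA with the full validation
    suite (training R-squared, 5-fold cross-validated Q-squared, label
    permutation testing, and VIP feature-importance scores). Also includes
    assay arithmetic for percent enzyme inhibition and pairwise-combination
    percent-improvement (synergy) statistics applicable to both inhibition
    percentages and docking-score magnitudes, and a class-structured
    compositional data generator for end-to-end testing of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
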