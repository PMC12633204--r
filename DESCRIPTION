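Package: foodreadout
Title: Reference-Based Dietary Readout from Untargeted Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Learns food-category-specific MS/MS ion biomarkers from a
    reference food metabolomics dataset using one-vs-rest OPLS-DA across a
    hierarchical food ontology, with Variable Importance in Projection (VIP)
    and fold-change co-filters. Query MS/MS spectra from biological samples
    are matched against the resulting biomarker library by cosine or
    modified-cosine similarity, and matches are converted into per-sample,
    per-food-category dietary scores. Downstream statistics include PCA,
    permutation multivariate analysis of variance (PERMANOVA) and Pearson
    correlation of dietary scores against sample metadata with
    Benjamini-Hochberg control. A synthetic-data generator with planted
    ground truth supports end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vegan
Suggests:
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
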