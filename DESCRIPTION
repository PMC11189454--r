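Package: roicrosstalk
Title: Compartment-Resolved ROI Transcriptomics and Paired Ligand-Activity Inference
Version: 0.1.0
Authors@R: person("BCON", "Spatial Analysis Team", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for segmented region-of-interest (ROI) spatial
    transcriptomics of tumour tissue: ROI and gene quality control, third-quartile
    (Q3) normalisation, empirical-Bayes moderated differential expression,
    signature-matrix cell-type deconvolution by non-negative least squares,
    nearest-centroid molecular subtyping with an undefined class, weighted
    signalling-network path inference, and a paired sender-to-receiver
    ligand-activity statistic: the mean Pearson correlation between a ligand's
    expression in sender profiles and its prior targets' expression in paired
    receiver profiles, with mean r >= 0.2 calling an actively signalling ligand.
    Includes a synthetic-data generator that plants known ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
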