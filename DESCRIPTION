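Package: r2sn
Title: Regional Radiomics Similarity Networks for MCI Subtyping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Constructs individual regional radiomics similarity networks
    (R2SN) from labeled 3D volumes or regional feature tables, selects
    disease-consistent network edges by combining edgewise statistics with
    linear-classifier weights, clusters mild-cognitive-impairment patients
    into two subtypes by rank-2 nonnegative matrix factorization,
    characterizes the subtypes (clinical contrasts, CSF biomarker
    categories, longitudinal trajectories, Kaplan-Meier/log-rank conversion
    analysis), and relates the subtype difference map to regional gene
    expression via partial least squares. Ships a synthetic-cohort
    generator so the whole pipeline is exercisable and testable without
    access-gated imaging or transcriptomic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    survival,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
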