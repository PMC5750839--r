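Package: shapefish
Title: Ligand-Based Protein Target Fishing by Gaussian Shape and
    Pharmacophore Similarity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts protein targets for a query compound by weighted
    first-order Gaussian 3D shape and pharmacophore-feature similarity
    against a curated database of target-annotated ligands (reverse
    virtual screening, "target fishing"). Provides atomic-Gaussian shape
    models with closed-form overlap volumes and analytic gradients,
    rigid-body pose optimization from inertial starting orientations,
    shape/feature/combination Tanimoto scores, bioactivity database
    curation with potency and size filters, ranked target prediction
    with similarity and activity thresholds, aligned-pose export, and a
    deterministic synthetic-fixture generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    igraph,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
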