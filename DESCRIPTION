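Package: PNPWorkbench
Title: Chemoinformatic and Morphological Profiling Analytics for
    Pseudo-Natural-Product Collections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis toolkit for characterizing pseudo-natural-product
    (PNP) compound collections and their phenotypic screening readouts.
    Provides compound collection input/output with canonicalization,
    molecular descriptor panels, drug-likeness (QED), natural-product
    likeness trained from fragment contributions, the spatial complexity
    score (SPS/nSPS), principal-moments-of-inertia shape analysis and
    circular-fingerprint Tanimoto similarity; chemical-space embeddings
    (PCA, UMAP) and substructure enrichment; cell-painting profile
    analytics (robust z-score profiles, induction, biosimilarity, cluster
    subprofile extraction and assignment); Seahorse mitochondrial stress
    test trace summarization; and seeded synthetic-data generators with
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    uwot
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    pROC
SystemRequirements: python (>= 3.8) with the rdkit package on the PATH
    (override the interpreter via the PNPWORKBENCH_PYTHON environment
    variable)
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'backend.R'
    'compound-io.R'
    'descriptors.R'
    'nplikeness.R'
    'fingerprints.R'
    'chemspace.R'
    'profiles.R'
    'subprofiles.R'
    'bioenergetics.R'
    'synthetic.R'
    'workbench.R'
    'PNPWorkbench-package.R'
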