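Package: minidep
Title: Desk-Scale Biocuration Pipeline for Macromolecular Structure Depositions
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A self-contained, desk-scale re-creation of the curation
    pipeline used for macromolecular structure depositions: a
    dictionary-driven validation engine for a PDBx/mmCIF subset (types,
    enumerations, mandatory items, parent/child key integrity, hard and
    soft numeric limits), entity transformation (polymer/non-polymer
    classification, backbone-link detection, chain split/merge, peptide
    reference matching and polymer/ligand representation transforms),
    ligand identification by element-labelled sub-graph isomorphism
    against a packaged chemical component dictionary with atom-name
    standardization and chirality checking, sequence reconciliation
    (coordinate-derived sequence, reference cross-referencing, controlled
    discrepancy annotation, chimera segmentation, residue-label repair),
    value-added structural annotation (solvent repositioning under
    crystal symmetry, covalent link generation, secondary-structure
    assignment, assembly expansion, hetero renumbering, extended quality
    checks), and a workflow manager (stage state machine, geographic
    routing, release-policy calendar, percentile scores, report and
    letter compilation). All inputs, including worked-example
    depositions with planted defects, are generated by a seeded fixture
    factory; no network access is required.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    lubridate,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'findings.R'
    'AllClasses.R'
    'AllGenerics.R'
    'mmcif.R'
    'schema-io.R'
    'dictionary.R'
    'deposition-io.R'
    'entity.R'
    'ligand.R'
    'prd.R'
    'sequence.R'
    'annotate.R'
    'workflow.R'
    'fixtures.R'
    'pipeline.R'
    'minidep-package.R'
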