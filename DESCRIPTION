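Package: hbq
Title: Hydrogen-Bond Distance QSAR and Docking Pose Analysis for Channel Blockers
Version: 0.1.0
Author: hbq developers
Maintainer: hbq developers <hbq-dev@example.org>
Description: Links minimized ligand-protein-water complex structures to
    percent channel inhibition through hydrogen-bond geometry. Reads
    fixed-column atom records, detects direct and water-bridged
    ligand-protein polar contacts at a distance cutoff, assembles a
    chain-agnostic residue-keyed bond-length feature matrix, and selects
    fixed-size variable subsets for multiple linear regression with a
    genetic algorithm scored by the determination coefficient. Also
    provides energy-seeded leader clustering of docking poses with
    coverage-based representative selection, a one-parameter
    dose-response model for IC50 estimation, group summaries for
    cyst-growth assays, and synthetic-data generators with planted truth
    for end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
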