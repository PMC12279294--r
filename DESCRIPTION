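Package: cdrclust
Title: Clustered Generative Ensembles of Antibody Loop Conformations for Docking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reduces large generative ensembles of antibody heavy-chain models
    to small, structurally diverse ensembles suitable for information-driven
    docking. Provides framework-aligned CDR loop backbone RMSD, deterministic
    agglomerative clustering with medoid cluster centers, heavy/light chain
    assembly with a van-der-Waals backbone clash filter, pLDDT-based triage of
    difficult targets, and CAPRI-standard evaluation of docking models (fnat,
    ligand RMSD, interface RMSD, quality classes, top-N success rates).
    Includes a deterministic generator of toy antibody-like fixtures with
    planted cluster structure, clashes, and confidence profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    mclust,
    bio3d,
    withr
Config/testthat/edition: 3
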