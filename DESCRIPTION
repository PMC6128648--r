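Package: thermoforest
Title: Random-Forest Prediction of Protein Thermostability Changes from
    Structure-Based Descriptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes amino-acid, local-structure and global-structure
    descriptor blocks for single-point protein mutants directly from PDB
    structures (Shrake-Rupley solvent accessibility, fraction buried,
    hydrogen-bond based secondary structure, naive mutant building),
    imports externally computed ddG energy terms, and trains random-forest
    regression models of the change in melting temperature (dTm) with
    repeated cross-validation, bootstrap model comparison, y-scramble
    importance significance testing, and an ensemble-variance
    applicability-domain criterion.  Ships a synthetic-data generator
    (ideal helices, beta hairpins, simulated mutant datasets) used for
    validation throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    randomForest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
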