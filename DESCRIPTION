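Package: SLiMBind
Title: Predicting Peptide-Binding Residues in Disordered Protein Regions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts, per residue, which positions inside a disordered
    protein region bind a structured peptide-binding domain. Overlapping
    short peptide fragments cut from a 50-residue candidate window are
    docked against the receptor structure; the best-pose affinities are
    aggregated into a per-residue track, normalised, and combined with
    predicted secondary structure and disorder inside a bidirectional
    recurrent neural network trained by ten-fold cross-validation with
    window-size ensembling. Includes receptor/search-box preparation from
    PDB structures with a bound peptide chain, a deterministic mock
    docking engine and synthetic-fixture generators for offline testing,
    residue-level ROC/AUC evaluation, and a proteome-scan workflow for
    motif regular expressions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
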