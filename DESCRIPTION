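Package: foldsteer
Title: Steering Protein Structure Predictions by Editing Predictor Inputs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and edits the input features consumed by
    AlphaFold2-style structure predictors (templates, multiple sequence
    alignments, query variants) so predictions can be steered toward chosen
    conformational states. Provides multi-chain assembly via residue-index
    linkers, MSA masking/subsampling/merging, template relabeling
    (polyalanine, query sequence) and C-beta truncation, point-variant
    cycles with template-based reversion, and a mosaic mode that splits
    large targets into overlapping sub-predictions and merges them.
    Ensemble analytics include pairwise structural correlation with a
    multidimensional-scaling embedding, rigid-group/hinge decomposition,
    Kabsch superposition, stereochemistry and compactness scoring,
    interface metrics, and model ranking. A deterministic mock backend
    makes every stage testable without a GPU or network access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    Biostrings,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
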