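Package: kmeopl
Title: Methyllysine Oriented Peptide Library Profiling and Proteome Motif Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for plate-based methyllysine oriented peptide
    library (Kme-OPL) reader assays: turns raw plate fluorescence into
    GST-subtracted pool results and normalized 6-position x 19-residue reader
    binding profiles, calls methyl-order preference, quantifies sequence
    specificity, scores every lysine-centered seven-mer in a proteome with the
    Lowest-Bin (LoB) minimum rule, predicts optimal and poor binding sequences,
    annotates hits with protein copy-number abundance, and fits fluorescence
    polarization titrations with a specific-binding-with-Hill-slope model to
    estimate dissociation constants. Includes a synthetic-data generator that
    emulates the assay from a latent position-specific binding model so every
    stage is testable without wet-lab data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
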