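Package: lysocleave
Title: Cleavage-Site Prediction and In Silico Digestion for Phagolysosomal Proteases
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts cleavage sites of (phago)lysosomal endoproteases and
    simulates the resulting proteolytic digestion. Proteases with many known
    substrates are modelled by position-specific scoring matrices (PSSMs)
    trained over five parallel feature alphabets (amino acid identity, charge,
    hydropathy, secondary structure and solvent accessibility); proteases with
    few substrates are matched by consensus cleavage patterns over the P4-P4'
    window. Includes complete, partial and sequential digestion simulation
    with peptide mass and isoelectric-point annotation, the full training and
    evaluation protocol (homology filtering, substrate-level splitting,
    imbalanced and under-sampled labelled sets, precision-recall threshold
    calibration), a synthetic substrate-corpus generator with planted cleavage
    motifs, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
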