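Package: hydrocascade
Title: Transmembrane Topography Prediction by Cascade-Averaged Hydropathy Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts transmembrane domains (TMDs) and other hydrophobic
    regions of alpha-helical membrane proteins from primary sequence alone.
    A protein is encoded as a per-residue hydrophobicity series on one of
    seven bundled hydropathy scales, smoothed by cascade box averaging
    (pass n uses a centred window of width 2n+1 applied to the previous
    pass), and segmented by crossings of a threshold level, by default the
    whole-chain mean of the raw series. Includes signal-peptide flagging,
    Remark-style splitting of merged domains, a boundary-agreement
    evaluator against reference annotations, a planted-topography
    sequence simulator, FASTA/TSV/BED/GFF3 input and output, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    optparse,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
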