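Package: pmiscale
Title: Transmembrane Segment Prediction and Signal Peptide Discrimination
    with Learnable Hydropathy Scales
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sliding-window prediction of transmembrane (TM) helices and
    discrimination of signal peptides from signal anchors using per-residue
    hydropathy-like scales, including the translocon-derived PMIscale. A
    fixed-length window (default 23 residues) is scanned along a protein and
    scored by the mean scale value of its residues; the per-sequence maximum
    ("PMI value") separates signal peptides from membrane-inserted segments,
    and a two-threshold greedy scan localizes TM segments along full
    proteins. The package also provides the grouped steepest-ascent local
    search that learns such a 20-value scale from labeled examples by
    maximizing ROC AUC, a seeded synthetic-data generator emulating the
    structure of signal-peptide and signal-anchor training sets, FASTA and
    annotation input/output, TSV/GFF3 exports, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
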