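# Converted benchmark datasets

The published SP/TM benchmark datasets (SWPLearning, SWPTest, ScampiHigh,
ScampiLow, PDBTMSeg) are third-party supplementary data and are not
redistributed with this package. To run the quantitative benchmark tests,
convert each dataset to FASTA — either with an `SP`/`TM` class token in each
header, or with a sidecar annotation TSV (`<name>.fasta.annotations.tsv`
with columns `id`, `label`, optional `tm_start`, `tm_end`) — and place it
here as `<name>.fasta` (e.g. `SWPTest.fasta`). `sniff_supplementary()`
auto-detects either dialect.
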