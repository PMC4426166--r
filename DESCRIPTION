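Package: tfoverlay
Title: Overlapping Transcription-Factor Target Networks with Expression Overlays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds overlapping transcription-factor (TF) target networks from
    ChIP-seq derived target lists or raw peak tables, overlays per-gene
    expression statistics (log2 fold change, unpaired t-test p-values),
    numerically filters the network to a human-readable sub-network, lays it
    out with a TF-circle / fixed-region-box algorithm in which target genes are
    grouped by their Venn membership among the TFs, and renders the result to
    PNG, GIF or SVG. Reads and writes edge tuples, two-column gene/value
    tables, COD-style peak lists, GEO SOFT expression files and GraphML, and
    ships a synthetic-data generator with exact Venn-region counts and planted
    fold changes for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    xml2,
    yaml,
    jsonlite,
    png,
    withr
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
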