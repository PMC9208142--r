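Package: proteoval
Title: FDR Control and Transcriptome-Informed Filtering for Bottom-Up Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for validating peptide-spectrum matches (PSMs) in
    bottom-up proteomics and for transcriptome-informed reduction and
    filtering of protein sequence databases. Implements score-cutoff
    estimation by target-decoy competition with the (d+1)/t estimator and
    by the Benjamini-Hochberg step-up procedure, decoy database generation
    by sequence reversal, PSM validation prefilters (pretty rank, single
    best PSM per query, minimum peptide length), construction of reduced
    protein databases from transcript expression, bipartite peptide-protein
    graph analysis of protein-inference ambiguity via connected components,
    post hoc transcriptome-informed filtering of identifications,
    spectrum-level comparison of paired database searches (reallocation and
    additional-identification accounting), and a ground-truth simulator for
    calibration experiments contrasting the two FDR control methods across
    database sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
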