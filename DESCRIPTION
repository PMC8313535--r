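Package: tcrgd
Title: Paired Gamma-Delta T-Cell Receptor Repertoire Analysis
Version: 0.1.0
Authors@R: person("Repertoire", "Tools", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of paired single-cell gamma-delta T-cell receptor
    (TCR) repertoires: ingestion of AIRR Rearrangement TSV and 10x-style
    filtered-contig tables, productive-chain filtering and per-cell
    chain pairing, amino-acid-level clonotyping with detection of
    convergent recombination, Hill-number diversity (species richness
    and exponential Shannon entropy) with rarefaction, extrapolation and
    coverage-adjusted bootstrap confidence intervals, the D50 clonality
    index, V/J gene-usage contingency tests, clonotype sharing within
    and across intestinal segments, integration of clonotypes with
    per-cell transcriptome cluster labels, and a synthetic-repertoire
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
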