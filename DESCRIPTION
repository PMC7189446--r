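Package: territoria
Title: Polyploid Chromatin Architecture from Hi-C Contact Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of binned Hi-C and Hi-ChIP contact matrices from
    allopolyploid genomes: ICE iterative balancing, genome-territory
    interaction statistics (Mann-Whitney U, Cliff's Delta) over 10-Mb
    super-bins with subgenome and homeolog classification, insulation-index
    computation and calling of condensed folding domains (ICONS),
    significance of intra- and interchromosomal chromatin loops from a
    coverage-corrected distance-decay Poisson model with Benjamini-Hochberg
    FDR control, a gene-pair feature-association ledger (odds ratios,
    Cramer's V, expression quantile concordance, partner counts), and
    loop-conditioned coregulation regressions of partner log2 fold changes.
    Includes a synthetic polyploid generator that plants subgenome
    territories, Rabl signal, condensed domains, gene-to-gene loops and
    coupled expression so that every statistic can be validated by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    yaml,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
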