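Package: multilocus
Title: Multi-Gene Alignment Containers and Phylogenetic Incongruence Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Containers and tools for phylogenetics with multiple genes.
    Provides an S4 container that harmonizes individuals across per-locus
    sequence alignments (gap-padding missing taxa), matrix-like subsetting
    and supermatrix concatenation, MLST-style haplotype allele coding and
    SNP extraction into genotype tables, pairwise-deletion genetic
    distances (raw, p, JC69, K80), neighbour-joining trees per locus or on
    the concatenated alignment, Robinson-Foulds incongruence comparison,
    multi-panel alignment overview plots, and a synthetic-data simulator
    for multi-locus data sets with controlled missingness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    ape,
    phangorn,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'multilocus-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'locus.R'
    'container.R'
    'accessors.R'
    'patterns.R'
    'io.R'
    'markers.R'
    'dist.R'
    'trees.R'
    'viz.R'
    'fixtures.R'
    'cli.R'
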