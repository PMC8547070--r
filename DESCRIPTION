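Package: fruitsplice
Title: Comparative Alternative Splicing Analysis of Fleshy Fruit Development
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds high-quality non-redundant transcriptomes from per-stage
    assembled transcript models by a junction-support / expression /
    class-code / single-exon filter cascade, detects local alternative
    splicing events (intron retention, exon skipping, alternative 5' and 3'
    splice sites) from exon chains, quantifies percent-spliced-in (PSI) from
    transcript abundances and calls stage occurrence, stage-specific and
    differentially spliced events, resolves one-to-one orthologues from
    orthogroups with reciprocal-best-hit and synteny evidence, detects
    conserved splicing events across species by local alignment of
    junction-flanking exon sequences within orthogroups, and clusters
    per-sample binary splicing profiles over the orthologue index with the
    binary (asymmetric Jaccard) distance. Ships a seeded multi-species
    synthetic-data generator with a ground-truth manifest so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
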