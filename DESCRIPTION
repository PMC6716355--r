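Package: casecomm
Title: Casing-Soil 16S Community Analysis with Negative-Control Decontamination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for 16S rRNA amplicon community analysis of
    mushroom casing soil: paired-read merging and quality filtering, an
    iterative four-step negative-control decontamination of unique-sequence
    tables, greedy de novo OTU clustering at 97% identity, seeded rarefaction,
    alpha diversity (Shannon, ACE), Hellinger/Bray-Curtis ordination with NMDS
    and ANOSIM, Kruskal-Wallis plus LDA-effect-size biomarker discovery, and
    Spearman co-occurrence networks. Includes a synthetic-data generator that
    emulates a staged cultivation sampling design with reagent-style
    contamination, so the full pipeline is testable without external
    sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    Biostrings,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    cluster
Config/testthat/edition: 3
RoxygenNote: 7.3.3
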