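Package: SynComSelect
Title: Function-Based Design of Synthetic Microbial Communities
Version: 0.1.0
Authors@R: person("SynComSelect", "Developers", role = c("aut", "cre"),
    email = "syncomselect@example.org")
Description: Selects fixed-size synthetic communities (SynComs) of microbial
    strains whose combined protein-family (Pfam) repertoire best represents a
    group of metagenomes. Parses HMMER tabular annotations into binary Pfam
    presence/absence profiles, weights core and differentially prevalent
    functions (Fisher exact test of prevalence), performs per-sample iterative
    greedy selection with masking, shortlists strains by selection prevalence,
    enumerates and taxonomy-filters candidate consortia, ranks them by mean
    group score, and screens the ranked list for ecological viability using
    rule-based classification of pairwise growth interactions. Includes seeded
    synthetic-data generators for every input so the full pipeline runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
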