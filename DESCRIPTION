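Package: fourc
Title: 4C-seq Contact Profiles, Anchor-Based Differential Contacts and
    Allelic Expression Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for one-viewpoint chromosome conformation
    capture (4C-seq) built on a frag-end reduced genome: in-silico double
    restriction digestion, extraction and uniqueness annotation of the
    sequences flanking primary restriction sites (frag-ends), exact-match
    assignment of reading-primer-tagged reads, removal of the
    highest-coverage frag-end, read-depth normalization to one million
    intrachromosomal reads, running-mean smoothing over 21 consecutive
    frag-ends, and an anchor-based two-sample Student's t test of summed
    normalized coverage between genotype groups. Also provides
    reference-gene (geometric mean) normalization of RT-qPCR-style
    expression tables, a two-allele activity model for enhancer-deletion
    expression changes, and seeded synthetic-data generators (genomes with
    controlled restriction-site density, distance-decay 4C read sets with
    genotype-specific effect regions, and expression cohorts) so that every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
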