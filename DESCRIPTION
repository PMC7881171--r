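Package: replaceq
Title: Design and Quantification of NHEJ-Based Replace Genome Editing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-cut CRISPR/Cas9 "Replace" editing, in which a
    genomic segment is excised and a donor sequence is ligated in its place
    by non-homologous end joining. Provides cut-site arithmetic and
    enumeration of all expected post-editing allele structures, validation
    of directional (re-cuttable) designs, a truth-tagged synthetic read
    simulator with a staggered-cut junction mutation model, structural
    variant classification of long-read amplicons with per-base deletion
    profiles, UMI-based quantification of editing outcomes from
    single-primer linear amplification libraries, donor integration-site
    mapping with concatemer detection and off-target proximity analysis,
    and the closed-form allele-fraction arithmetic used to convert FACS
    measurements between ploidies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
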