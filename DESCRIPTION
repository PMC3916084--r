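Package: snvproteo
Title: Cohort SNV Filtering, Protein-Level Annotation and SNV-Based Phylogenetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-variant-calling toolkit for tumor/normal exome cohorts.
    Filters per-sample SNV calls on read depth, call quality and target
    regions; annotates substitutions onto transcript models to codon-level
    consequences and protein coordinates; classifies cohort variants as
    novel or known against a catalog, common or rare, and shared or unique
    between case and control arms; maps non-synonymous variants onto
    functional sites including N-linked glycosylation sequons (N-X-S/T)
    with motif-loss detection; tests annotation sets (domains, pathways)
    for over- or under-representation of variants under a uniform-placement
    null; and builds neighbor-joining phylogenies from SNV-shrunk genome
    alignments with bootstrap support. Includes a deterministic synthetic
    cohort generator so the whole workflow is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    vcfR,
    ape,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    pracma,
    jsonlite,
    optparse
Config/testthat/edition: 3
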