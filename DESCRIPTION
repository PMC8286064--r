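Package: irpannot
Title: Structural Annotation and Classification of Insulin/IGF-Related
    Peptide Precursors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative structural annotation of insulin/IGF-related
    peptide (irp) precursors and their candidate receptors. Implements
    rule-based prohormone convertase cleavage-site prediction (furin and
    neuroendocrine dibasic rules with contextual exclusions), detection of the
    canonical six-cysteine insulin framework and disulfide-bridge inference,
    precursor domain segmentation (signal/F/B/C/A/D/E), evidence-weighted
    classification into five irp families (IGF, GSS, octinsulin, dilp7
    orthologs, multinsulins), intron-phase and gene-structure diagnostics from
    GFF3 gene models, microsynteny cluster detection, neighbor-joining
    sequence-similarity trees from global alignments, and annotation of
    LGR-type receptor ectodomains (LDLa and leucine-rich repeats, hydropathy
    based transmembrane segments). A deterministic synthetic-data generator
    emulates all five precursor families, their gene structures, synteny
    layouts and receptor architectures so that every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
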