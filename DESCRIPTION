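Package: svarbiter
Title: Read-Evidence Annotation and One-Class Classification of Structural Variant Candidates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds high-confidence structural-variant (SV) call sets from
    candidate deletions and insertions by computing read-evidence annotations
    (coverage, soft-clipping, insert size, discordant and mate-unmapped pair
    fractions, long-read indel rates, GC/repeat/SNP context) in five windows in
    and around each candidate, across one or more aligned-read datasets.
    Candidates are scored against one-class models trained on random genomic
    regions: an empirical L1 distance-to-centroid classifier and a one-class
    SVM variant, combined across sequencing technologies with a k-of-n
    ensemble, pre-filters, and evidence stratification. Includes hierarchical
    clustering (Manhattan distance, Ward linkage) with MDS embedding for
    exploratory grouping of candidates, random-region samplers, interval-set
    utilities (deduplication, reciprocal-overlap matching), and a deterministic
    read simulator so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    e1071,
    data.table,
    vcfR,
    yaml,
    stats,
    utils,
    methods,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
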