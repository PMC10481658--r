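Package: PromCoRe
Title: Promoter-Centric Transcription Factor Co-Recruitment Networks
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers the architecture of cell-identity transcription factor
    (TF) networks from promoter binding patterns. Cistromes (ChIP-seq peak
    sets) are merged into cis-regulatory modules, intersected with active
    transcription start sites to build a binary promoter-by-regulator
    binding matrix, and clustered with a toroidal self-organizing map
    followed by Ward cuts of binarized cell prototypes. Co-recruitment
    structure is quantified with Tanimoto distance matrices, classical
    multidimensional scaling, frequent-itemset core nodes and distance
    correlation. Expression programs (cell-type specific, enriched,
    ubiquitous) are called by multiple factor analysis of multi-species
    expression atlases, and identity-connected TFs are selected by focal
    cell rank and fold difference. Activity-matched control gene sets,
    rank-based group tests, and a batch-corrected PCA projection onto a
    reference differentiation axis complete the downstream statistics. A
    synthetic-data generator with serialized ground truth makes every stage
    verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
biocViews: Epigenetics, Transcription, GeneRegulation, Clustering,
    ChIPSeq, Network
RoxygenNote: 7.3.3
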