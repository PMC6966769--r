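Package: vshapes
Title: Co-Regulatory Network Inference by Minimum-Weight V-Shape Selection
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates an affinity transcriptional regulatory network
    (position-specific scoring matrix scans of promoter intergenic regions
    with exact match p-values, operon prediction by intergenic distance)
    with a pathway-annotated metabolic gene set. Confident co-regulatory
    arcs are selected as members of minimum-weight V-shapes connecting
    metabolic operons of the same pathway category, and the resulting
    co-regulatory network is characterised topologically: simple cycles,
    minimum feedback arc sets, hierarchy levels, tree distance, primary
    regulators, reachability and exclusivity tables, and minimal
    controlling regulator sets. A synthetic-data generator with planted
    ground truth makes every stage testable end to end.
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
    Biostrings,
    rtracklayer,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: NetworkInference, GeneRegulation, Transcription, GraphAndNetwork
RoxygenNote: 7.3.3
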