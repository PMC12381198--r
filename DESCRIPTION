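Package: ztnet
Title: Time-Course RNA-Seq Co-Expression Communities and Misregulation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale implementation of a diel time-course RNA-seq
    analysis chain for genotype-by-temperature experiments: negative-binomial
    per-timepoint differential expression with Benjamini-Hochberg FDR control,
    CPM normalization with trimmed-mean-of-M-values factors, Pearson
    co-expression networks thresholded at PCC > 0.9, Girvan-Newman
    edge-betweenness community detection with a maximum-modularity dendrogram
    cut, community-level genotype-by-time misregulation scoring by two-way
    ANOVA with Tukey HSD, promoter motif counting and binding/overlap
    enrichment by the hypergeometric test, and flowering phenotype indices
    (total leaf number, leaves per day, leaf number ratio, delta-delta-Cq).
    A seeded synthetic-data generator with planted co-expressed communities,
    promoter motifs, binding tables and phenotypes makes every stage
    verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    igraph,
    car,
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
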