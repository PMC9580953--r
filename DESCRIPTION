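Package: pangenomics
Title: Bacterial Pan-Genome Partitioning, Accumulation-Curve Modelling and
    Probiotic Trait Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative bacterial genomics at the gene-family
    level: ortholog clustering of protein sets via a similarity graph and
    Markov clustering, classification of gene families into core, accessory
    and strain-specific subsets, permutation-based pan- and core-genome
    accumulation curves with Heap's-law (open/closed call) and
    offset-exponential (core-genome plateau, new-genes-per-genome) model
    fits, and downstream annotation summaries (functional-category
    distributions, trait-gene presence/absence heatmaps, localization by
    adhesin-score cross-tabulations, and score-filtered protein-protein
    interaction network summaries). Includes a synthetic pan-genome
    generator with known ground truth and a reproducible end-to-end
    pipeline with manifest-tracked outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pheatmap,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
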