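Package: ksdater
Title: Detection and Dating of Whole-Genome Duplications from Transcriptome Ks Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and dates ancient whole-genome duplication (WGD) events
    from a de novo transcriptome. Paralogous gene pairs are identified from
    all-by-all similarity hits, clustered into gene families by single
    linkage, and each family is decomposed into node-wise synonymous
    distances (Ks) so multicopy families are not over-weighted. Pairwise Ks
    and Ka are estimated from protein-guided codon alignments with the
    Nei-Gojobori (1986) counting method and a reimplementation of the Yang
    and Nielsen (2000) approximate method. Normal mixture models are fitted
    to ln(Ks) by multi-start EM with BIC/AIC model selection, and component
    medians are converted to absolute divergence times with a synonymous
    molecular clock. Also provides transcriptome assembly QC statistics
    (N50, length histograms, coverage depth, Ortholog Hit Ratio), a
    hit-guided CDS extraction/translation step with protein quality filters,
    and a synthetic-data generator (codon-level substitution simulator,
    lognormal Ks mixtures, toy hit tables) so the whole pipeline is testable
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
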