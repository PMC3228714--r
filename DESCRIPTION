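Package: uridiv
Title: Amplicon Diversity Pipeline for Culture-Negative Urine Microbiota
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A 16S rDNA amplicon diversity pipeline for low-biomass,
    culture-negative urine specimens sequenced as pyrosequencing-style
    reads. Implements primer-based region splitting and trimming,
    dereplication, an abundance-ranked sequence-space denoiser for
    homopolymer-run indel errors, negative-control contamination
    filtering by joint complete-linkage clustering with read-count
    weighting, Needleman-Wunsch pairwise distances with free terminal
    gaps, abundance-weighted hierarchical OTU clustering, Chao1 richness
    with log-normal confidence intervals, Shannon and subsample-normalized
    Shannon diversity, analytic rarefaction, and lowest-common-ancestor
    taxonomic assignment with bit-score, top-percent and minimum-support
    rules. A synthetic community and read simulator with known ground
    truth makes every stage testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
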