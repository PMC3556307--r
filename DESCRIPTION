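Package: ultracons
Title: Discovery and Comparative Analysis of Ultraconserved DNA Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for discovering ultraconserved DNA elements (UCEs)
    between repeat-masked genomes of distant species and characterizing them.
    Finds all maximal exact matches at a length threshold on both strands,
    merges overlapping elements into non-overlapping ultraconserved regions
    (UCRs) with flanking sequence, clusters UCRs by local-alignment score
    density with Markov clustering, embeds them by 5-mer composition with
    non-centered minimum curvilinear embedding, and scores protein-domain
    enrichment of nearby genes (cumulative hypergeometric) and 8-mer
    overrepresentation against species-proportional background sequence
    (cumulative binomial). Includes JTT maximum-likelihood protein distances
    with neighbor-joining and bootstrap support for the species phylogeny,
    and a synthetic-data generator that plants conserved elements, repeats,
    gene annotations and JTT-evolved protein families with known ground
    truth so every stage is testable without external data.
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
    BiocGenerics,
    rtracklayer,
    ape,
    phangorn,
    igraph,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
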