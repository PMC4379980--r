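Package: ltrpipe
Title: Structural Annotation, Dating and Redundancy Analysis of LTR Retrotransposons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: De novo structural detection of full-length LTR retroelements in
    assembled contigs (paired long terminal repeats with TG...CA termini,
    target-site duplications, primer-binding sites and polypurine tracts),
    superfamily classification from the order of internal protein domains
    (Copia vs Gypsy, with chromodomain detection), insertion-age dating from
    sister-LTR divergence under the Jukes-Cantor model with a substitution
    rate calibrated from ortholog synonymous divergence (Nei-Gojobori), and
    solo-LTR quantification from short-read coverage ratios. Includes a
    transposable-element insertion simulator with ground-truth manifests so
    every stage can be validated without external data, a neighbour-joining
    phylogeny of reverse-transcriptase domains, and summary tabulations of
    per-superfamily statistics, flank contexts and age distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
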