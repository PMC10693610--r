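Package: allopolykit
Title: Polyploidy Origin and Subgenome Divergence Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing the mode and timing of ancient whole-genome
    duplication in tetraploid plant genomes. Implements Nei-Gojobori (NG86)
    Ka/Ks estimation with Jukes-Cantor correction, Gaussian-mixture dating of
    Ks distributions, the collinear gene-quartet topology test for a shared
    allotetraploidy event, a Ks-asymmetry test separating allo- from
    autotetraploid origins, LTR retrotransposon insertion-time dating
    (T = K/2r), subgenome fractionation-bias statistics, homoeolog
    expression-bias classification, and cross-species orthologous-DEG
    concordance. Includes a seeded codon-level sequence simulator so every
    stage can be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    ape,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
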