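Package: mitoclover
Title: Comparative Mitogenomics of Insect Mitochondria with tRNA-Like
    Structure Detection in Control Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated insect mitochondrial
    genomes: nucleotide composition and strand-asymmetry statistics (AT/GC
    skew), codon-usage bias metrics under the invertebrate mitochondrial code
    (RSCU, effective number of codons, codon bias index, ENC-plot expectation),
    pairwise Ka/Ks estimation (Nei-Gojobori with Jukes-Cantor correction),
    control-region repeat cataloguing (tandem repeats, poly-T tracts, TA
    repeats, G+C-rich windows), and detection of tRNA-like structures by
    constrained cloverleaf folding with an anticodon-identity criterion.
    Includes a deterministic synthetic mitogenome generator with planted
    ground truth, a pipeline driver, and phylogenetic supermatrix export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
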