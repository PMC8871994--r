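Package: protogenr
Title: Characterization of De Novo Proto-Genes by Genomic Position and Age
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for characterizing de novo transcribed ORFs
    (proto-genes): classification by genomic position (exonic/intronic/intergenic)
    and age class, intron structure and intron-recycling detection via local
    alignment with Karlin-Altschul E-values, PFM/PWM/PSSM regulatory-motif
    scanning of upstream and core-promoter windows with promoter/enhancer
    partitioning, 5'/3' UTR GC and RNA fold-ensemble statistics (minimum free
    energy, ensemble free energy, MFE frequency, ensemble diversity) from a
    simplified nearest-neighbour folder with an exhaustive enumeration oracle,
    hydrophobic-cluster analysis of proto-proteins, and the accompanying
    statistical toolkit. Ships a seeded synthetic genome/annotation generator
    that plants ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
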