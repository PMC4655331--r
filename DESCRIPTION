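Package: cehkit
Title: Characterization of Conserved Extended Haplotypes in the Human MHC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing conserved extended haplotypes (CEHs)
    in the human major histocompatibility complex from multi-sample diploid
    variant calls. Provides window-based zygosity profiling and
    conserved-stretch calling, a runs-of-homozygosity scan, haploid consensus
    construction with intra- and inter-haplotype variant catalogues,
    feature-class annotation with coding-effect translation, nucleotide
    diversity and star-genealogy haplotype-age estimation, pairwise r2
    linkage-disequilibrium block detection with block haplotype tables,
    co-segregation screening against binary phenotypes, Kimura 2-parameter
    neighbor-joining phylogenies with bootstrap support, and calibrated qPCR
    relative copy-number calling for the RCCX module. A synthetic-cohort
    generator with full ground truth supports end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    seqinr,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
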