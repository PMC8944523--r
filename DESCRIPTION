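Package: genefamkit
Title: Gene Family Characterization Toolkit for Plant Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end toolkit for characterizing plant gene families
    (e.g., superoxide dismutase and glutathione peroxidase) from genome
    bundles: domain-based identification and naming of family members,
    physicochemical protein properties, neighbor-joining phylogenetics with
    bootstrap support, exon-intron structure and promoter cis-element
    scanning, tandem/segmental duplicate classification, Nei-Gojobori
    Ka/Ks selection inference and synonymous-rate divergence dating, and
    FPKM/qPCR expression analysis with Duncan's multiple range test.
    Includes a synthetic-bundle generator with known ground truth for
    validating every stage without external genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
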