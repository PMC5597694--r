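Package: panmhc
Title: MHC Class I Allele Cataloguing and Nucleotide Diversity Analysis for Pan
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing full-length MHC class I alleles in
    chimpanzees (Patr-) and bonobos (Papa-): parsing and collapsing
    colon-delimited allele nomenclature at full-length, coding and protein
    resolution; exon/intron gene models with CDS extraction and translation;
    nucleotide diversity (pi) with standard errors for arbitrary region
    selections over diploid genotype sets; an individual-resampling
    permutation test for between-taxon diversity differences with Bonferroni
    correction; reconciliation of duplicate PCR-replicate allele calls with
    detection of spurious frameshifting deletion alleles; and a synthetic
    diploid-genotype simulator with region-heterogeneous mutation density
    for end-to-end validation. Ships transcribed genotype tables from a
    published survey of 30 chimpanzees and 21 bonobos and reproduces its
    allele counting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
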