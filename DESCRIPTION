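Package: hapsnp
Title: Haplotype-Based SNP Detection from Read Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reference-free detection of reliable single-nucleotide
    polymorphisms from multi-read alignments in SAM/BAM or ACE format.
    Candidate variants pass three successive filters: a minimum read-support
    threshold, a base-quality filter with optional homopolymer and read-end
    masking, and a haplotype-support filter in which reads are clustered into
    haplotypes over the high-confidence sites and only variants backed by
    reconstructed haplotypes are retained. The package genotypes samples via
    SAM read groups or read-name labels, corrects haplotype counts for
    fragmentation, exports marker SNPs with flanking sequence for assay
    design, persists results as reloadable CSV files, and ships a
    command-line interface plus a read simulator with planted haplotypes and
    platform-style errors for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    optparse,
    Rsamtools,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
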