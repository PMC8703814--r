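Package: ssrgbs
Title: Microsatellite Genotyping by Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for genotyping simple sequence repeat (SSR,
    microsatellite) markers from paired-end amplicon sequencing reads
    ("SSR-GBS"). Paired reads are merged into amplicons, demultiplexed by
    primer sequence, and alleles are scored as digital fragment lengths.
    Diploid genotypes are called with a per-marker first-allele frequency
    threshold (alpha), which is calibrated together with capillary
    electrophoresis (CE) size offsets against a reference genotype
    database; markers affected by allele dropout, stutter artifacts or low
    read depth are flagged and filtered. Locus summary statistics
    (observed and expected heterozygosity, polymorphism information
    content), variety discrimination checks, shared-allele distances and
    UPGMA dendrograms support cultivar identification. A paired-read
    simulator with PCR stutter, slippage, amplification bias and allele
    dropout provides ground truth for validating the whole pipeline, and a
    reference marker survey of a 116-variety apple, pear and tea panel is
    bundled.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
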