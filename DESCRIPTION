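Package: dualseq
Title: Replicate-Consensus Analysis of Somatic Variant Calls from Dual Deep Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for separating real low-frequency somatic mosaic mutations
    from PCR-induced false positives by exploiting replicated deep sequencing.
    Somatic VCF call sets produced by several variant callers across libraries
    amplified with different DNA polymerases and sequenced in duplicate are
    normalized to a shared variant identity, intersected (three-set Venn
    grouping), and classified into four reproducibility categories based on
    how many polymerase libraries detect each variant in each replicate
    experiment. Additional modules quantify variant allele frequency
    concordance (between-run versus between-caller variability), compute
    capture-panel coverage metrics and read-downsampling saturation curves,
    and simulate complete dual-sequencing experiments with planted mosaic
    variants and library-specific polymerase-error false positives so the
    whole workflow can be validated against a known truth set.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
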