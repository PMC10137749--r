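Package: umisnp
Title: UMI-Aware SNP Genotyping, Mixture and Kinship Analysis for
    Forensic Sequencing Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for massively parallel sequencing of large forensic SNP
    panels tagged with unique molecular indices (UMIs). Groups reads by UMI,
    builds consensus (UMI) reads, tabulates allele depths with and without
    deduplication, and calls genotypes with allele-read-frequency (ARF)
    thresholds. Includes a molecule-level read simulator (Hardy-Weinberg and
    pedigree genotypes, template sampling from DNA input mass, branching PCR
    with substitution errors, sequencing errors, two-person mixtures), matched
    call-rate and matched error-rate comparison of UMI versus raw-read calling,
    DNA-mixture detection from heterozygosity rates and ARF distributions,
    quantitative mixture deconvolution with one known contributor, biallelic
    SNP kinship likelihood ratios (duo, trio, and kappa-based pairwise
    relationships) with gene-dropping simulations, and naive-Bayes
    biogeographic ancestry prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    vcfR,
    ggplot2,
    withr
Config/testthat/edition: 3
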