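Package: hornscan
Title: Selection Scans, Segregation Analysis and In Silico Genotyping for
    Horn Status Genetics in Sheep
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the genetics of horn status in sheep around
    the candidate insertion polymorphism in the 3'-UTR of RXFP2 on chromosome
    10. Implements a case/control windowed F_ST selection scan with
    identity-by-descent interval calling, a sex-influenced dominance model of
    horn inheritance with genotype-phenotype concordance tabulation over
    packaged breed panels, two-locus linkage disequilibrium (D, D', r2) from
    unphased genotypes via EM haplotype-frequency estimation, and in silico
    multiplex PCR and restriction-digest genotyping of presence/absence and
    SNP markers. A synthetic-data module generates genotype matrices, allele
    template sequences and breed panels with the structural properties the
    analyses assume, so the whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
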