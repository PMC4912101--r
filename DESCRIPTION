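Package: alupopdiv
Title: Gene Diversity, Genetic Distance and Population Structure from
    Biallelic Insertion/Deletion Polymorphisms
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for population-genetic analysis of presence/absence
    (insertion/deletion) polymorphisms such as human-specific Alu
    elements: allele frequencies by direct counting, observed and
    expected heterozygosity, Hardy-Weinberg chi-squared testing with
    Bonferroni correction, Nei's gene-diversity decomposition (Ht, Hs,
    Gst) with per-locus and multi-locus summaries, Nei (1972) and Da
    (1983) genetic distances with neighbor-joining trees and Newick
    export, and principal component analysis of population-by-locus
    frequency matrices. Includes a Balding-Nichols island-model
    simulator of genotype tables with known differentiation for
    end-to-end validation, and published allele-frequency and
    diversity values for twelve South Indian caste and tribal
    populations typed at seven Alu loci.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
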