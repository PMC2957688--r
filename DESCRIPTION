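Package: qhmap
Title: Quantitative Homozygosity Mapping from SNP Array Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Homozygosity mapping for localizing autosomal recessive
    disease genes from dense SNP genotype calls of patients born to
    consanguineous parents. Provides a closed-form error model for
    choosing the run-of-homozygous-SNPs (RHS) genetic-length cutoff,
    distance-based correction of mistyped heterozygous calls, RHS
    detection, Monte Carlo simulation of autozygous segments under
    Haldane's crossover model for a consanguinity loop (used to check
    reported inbreeding histories), multi-patient RHS overlap,
    case-control prioritization of overlaps, and gene-localization
    probabilities. A truth-annotated synthetic-data generator supports
    end-to-end validation without external genotype resources.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
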