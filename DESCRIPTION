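Package: dche
Title: High-Order Epistasis Detection by Dynamic Clustering of Genotype Combinations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-free detection of high-order (two- to four-locus) epistatic
    interactions in case-control genome-wide association data. Genotype
    combinations of a SNP tuple are greedily merged into three to six groups
    so as to maximise the significance of a Pearson chi-square test on the
    merged 2 x d table; a stepwise search scans all SNP pairs exhaustively
    with bitwise genotype encoding and extends the best candidates to higher
    orders. Family-wise error is controlled by a hybrid of Bonferroni
    correction across SNP tuples and a permutation-calibrated clustering-level
    budget. Includes a penetrance/odds disease-model simulator with prevalence
    and heritability constraints for power and type-I-error studies, quality
    control (missingness, minor allele frequency, Hardy-Weinberg equilibrium),
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
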