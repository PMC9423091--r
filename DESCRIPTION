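Package: polycrossGS
Title: Genomic Selection and Pedigree Reconstruction for Polycross Breeding Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for marker-based analysis of conifer polycross progeny
    trials: construction of realized additive (VanRaden) and dominance
    (Vitezica) genomic relationship matrices and their pedigree counterparts,
    SNP quality control and imputation, relationship-based pedigree
    verification and paternity assignment (including detection of
    dual-genotype mothers, pollen contamination, selfs and duplicates),
    individual-tree mixed models fitted by average-information REML with
    additive, dominance and site-interaction components and heterogeneous
    residuals, heritability and type-B genetic correlation estimation,
    breeding-value accuracy, and selection-gain and status-number accounting.
    A synthetic polycross trial generator with full ground truth supports
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
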