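Package: mlgblup
Title: Multi-Line Single-Step Genomic BLUP with Unknown Parent Groups and
    Metafounders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-line single-step genomic evaluation in
    livestock populations.  Implements pedigree relationship algebra
    (Henderson-rule sparse inverses, Meuwissen-Luo inbreeding, tabular
    relationships), unknown-parent-group machinery via the Quaas-Pollak
    transformation, metafounder relationships with a marker-estimated
    Gamma matrix, VanRaden genomic relationship matrices (observed- and
    0.5-frequency centering, SNP weighting, blending with pedigree
    relationships), the APY sparse inverse with eigenvalue-based core
    sizing, multi-trait mixed-model equations with missing-trait
    patterns, a BayesR Gibbs sampler for SNP weighting, GWAS-windowed
    variant preselection panels, LR-method validation of breeding
    values, and a seeded multi-line population simulator that generates
    the pedigree, genotype and phenotype structures the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
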