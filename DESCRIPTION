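Package: proxygwas
Title: Proxy-Phenotype (Family History) GWAS Toolkit with a Trio Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genome-wide association analysis using a relative's
    disease status as a proxy phenotype for the genotyped individual
    (GWAS-by-proxy). Implements construction of parental-history phenotypes
    with age-based exclusions, residualized additive linear-model
    association, conversion of linear coefficients to allelic odds ratios
    from trait prevalence and allele frequency with the two-fold log-odds
    rescaling appropriate for parent-offspring proxies, standard-error
    weighted fixed-effects meta-analysis with staged cohort designs and
    direction strings, linkage-disequilibrium based clumping into
    independent significant SNPs, lead SNPs and genomic risk loci,
    SNP-wise mean gene-based tests with an LD-aware null, Fisher exact
    gene-set enrichment, and validity diagnostics (genomic inflation,
    overlapping-control sensitivity, effect-size concordance, parameter
    recovery). A seeded trio-cohort simulator with Mendelian transmission,
    prevalence-calibrated logistic disease risk and informant-report
    misclassification provides ground truth for all of the above without
    any restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    jsonlite
Config/testthat/edition: 3
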