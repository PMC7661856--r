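Package: benefitscore
Title: Benefit Score Analysis Integrating Tumor Mutational Burden and
    Mutant-Allele Heterogeneity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes a per-tumor benefit score, the ratio of tumor
    mutational burden (TMB) to mutant-allele tumor heterogeneity (MATH),
    from MAF-style somatic mutation tables, and evaluates it as an
    immunotherapy response marker: quality and functional-class mutation
    filtering, MATH and clonal-TMB computation from cancer-cell-fraction
    annotations, patient stratification by the maximally selected log-rank
    statistic, Kaplan-Meier/log-rank/multivariate Cox survival analysis,
    Spearman marker correlations, and Wilcoxon contrasts of immune-cell
    fractions between score groups. Includes a synthetic-cohort generator
    with known clonal architecture, read-sampled variant allele fractions,
    score-linked survival and compositional immune fractions for
    calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    survival,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
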