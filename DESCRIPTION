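Package: gwasmr
Title: GWAS Summary-Statistics Meta-Analysis, Mendelian Randomization and
    Colocalization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A self-contained summary-statistics inference chain for
    protein-quantitative-trait GWAS: reading, quality-filtering and
    cross-cohort alignment of association results; fixed- and random-effects
    inverse-variance meta-analysis with Cochran Q / I-squared heterogeneity,
    genomic inflation and variance explained; greedy locus definition and an
    approximate conditional scan against an LD reference; simplified LD-score
    regression for the confounding intercept and SNP heritability with
    block-jackknife errors; exposure-outcome harmonization with palindrome
    handling, LD proxies and Steiger directionality filtering; the two-sample
    Mendelian randomization estimator suite (Wald ratio, fixed/random IVW,
    MR-Egger, weighted median, radial outlier detection); and Bayesian
    colocalization via Wakefield approximate Bayes factors. A synthetic-GWAS
    generator with known ground truth supports end-to-end recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
RoxygenNote: 7.3.3
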