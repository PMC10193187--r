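Package: mrpipe
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A config-driven pipeline for two-sample Mendelian randomization
    with GWAS summary statistics: instrument selection (genome-wide
    significance filtering, greedy LD clumping against a supplied r-squared
    matrix, chromosome exclusion), allele harmonization with palindromic-variant
    exclusion, the standard estimator suite (Wald ratios, fixed- and
    multiplicative-random-effects inverse-variance weighting, MR-Egger
    regression, the weighted median, and multivariable MR), MR-PRESSO global,
    outlier, and distortion tests, per-method Benjamini-Hochberg false
    discovery rates, odds-ratio scaling, binary-outcome power calculations,
    and a synthetic summary-statistics generator with controlled causal
    effects, pleiotropy, planted outliers, correlated exposures, and a
    clinically-diagnosed versus GWAS-by-proxy outcome pair for studying
    proxy-ascertainment bias.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
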