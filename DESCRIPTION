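Package: sexseldiv
Title: Sexual Selection and Reproductive Divergence in Experimental Evolution Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the strength of sexual selection and the
    divergent coevolution of male and female reproductive traits across
    replicate experimental-evolution lines. Implements the opportunity for
    sexual selection, Bateman gradients estimated in line-level mixed models,
    the Jones index, and a test of equal Bateman slopes between selection
    regimes; quasi-binomial crossed-design analysis of last-male sperm
    competition success (P2) with three complementary routes for comparing
    the male-by-female line interaction between regimes (a binomial mixed
    model variance component with fixed dispersion, a weighted
    arcsine-square-root linear mixed model variance-ratio test, and a
    residual cell-mean bootstrap with BCa intervals); and per-gene
    between-replicate expression divergence ratios with gene-set versus
    transcriptome-background tests and a best-hit ortholog filter for
    homology-search output. A synthetic-data generator with recorded ground
    truth makes every stage testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
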